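# Least-squares fitting of Scheffe polynomials on a power-transformed scale
# and Design-Expert-style adequacy statistics.

#' Fit a Scheffe polynomial to a transformed response
#'
#' Ordinary least squares of `power_transform(y, lambda)` on the Scheffe
#' model matrix of the design (no intercept). Validation-flagged runs in the
#' design are excluded from the fit and kept aside for
#' [holdout_validation].
#'
#' @param design A [mixture_design].
#' @param y Raw-scale response vector aligned with the design rows.
#' @param spec A [scheffe_spec].
#' @param lambda Power exponent of the modeling scale (default 1, identity).
#' @return Object of class `scheffe_fit`: coefficients, fitted values and
#'   residuals (transformed scale), hat diagonal, `SSE`, `MSE`, `n`, `p`,
#'   plus the training design, raw and transformed responses.
#' @examples
#' d <- builtin_design()
#' y <- simulate_responses(d, seed = 1)
#' fit_scheffe(d, y$encapsulation_pct, scheffe_spec(4, "linear", d$bounds$names))
#' @export
fit_scheffe <- function(design, y, spec, lambda = 1) {
  x <- design_matrix(design)
  train <- if (inherits(design, "mixture_design")) !design$is_validation
           else rep(TRUE, nrow(x))
  if (length(y) != nrow(x))
    mf_stop("response length does not match design", "mixformula_domain_error")
  x <- x[train, , drop = FALSE]
  y <- y[train]
  X <- scheffe_matrix(x, spec)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) mf_stop("need more runs than model terms (n > p)",
                      "mixformula_underdetermined")
  t <- power_transform(y, lambda)
  qrX <- qr(X)
  if (qrX$rank < p)
    mf_stop(paste0("singular information matrix; deficient term set: ",
                   paste(spec$labels, collapse = ", ")),
            "mixformula_singular_information")
  beta <- qr.coef(qrX, t)
  fitted <- drop(X %*% beta)
  resid <- t - fitted
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  SSE <- sum(resid^2)
  structure(list(
    spec = spec, lambda = lambda,
    coefficients = stats::setNames(as.numeric(beta), spec$labels),
    fitted = fitted, residuals = resid, hat = h,
    SSE = SSE, MSE = SSE / (n - p), n = n, p = p,
    design = x, run_ids = rownames(x), y = y, t = t),
    class = "scheffe_fit")
}

#' @export
print.scheffe_fit <- function(x, ...) {
  co <- x$coefficients
  eq <- paste(sprintf("%s %.2f %s", ifelse(co < 0, "-", "+"), abs(co),
                      names(co)), collapse = " ")
  cat("Scheffe fit on Y^", format(x$lambda), " scale (n = ", x$n,
      ", p = ", x$p, ")\n  t = ", sub("^\\+ ", "", eq),
      "\n  residual SD = ", sprintf("%.4g", sqrt(x$MSE)), "\n", sep = "")
  invisible(x)
}

#' Fit and adequacy statistics on the transformed scale
#'
#' Computes the response-surface summary statistics: residual SD
#' (\eqn{\sqrt{MSE}}), transformed-response mean, CV%, mean-corrected
#' \eqn{R^2}, adjusted \eqn{R^2}, PRESS
#' (\eqn{\sum (e_i/(1-h_{ii}))^2}, the leave-one-out shortcut), predicted
#' \eqn{R^2 = 1 - PRESS/SST}, and adequate precision
#' \eqn{(\max\hat y - \min\hat y)/\sqrt{p\,MSE/n}}. \eqn{R^2} uses the
#' mean-corrected total sum of squares even though the Scheffe matrix has no
#' intercept: the full set of linear blending terms spans the constant.
#'
#' @param fit A [scheffe_fit].
#' @return Object of class `fit_stats` with fields `std_dev`, `mean`,
#'   `cv_pct`, `r2`, `adj_r2`, `press`, `pred_r2`, `adeq_precision`. PRESS
#'   is `NA` (with a warning) when some leverage equals 1; adequate
#'   precision is `Inf` when `MSE` is 0.
#' @export
fit_statistics <- function(fit) {
  t <- fit$t
  n <- fit$n; p <- fit$p
  SST <- sum((t - mean(t))^2)
  SSE <- fit$SSE
  r2 <- 1 - SSE / SST
  adj <- 1 - (SSE / (n - p)) / (SST / (n - 1))
  if (any(fit$hat >= 1 - 1e-12)) {
    mf_warn("leverage of 1: PRESS undefined for this fit",
            "mixformula_press_undefined")
    press <- NA_real_
    pred <- NA_real_
  } else {
    press <- sum((fit$residuals / (1 - fit$hat))^2)
    pred <- 1 - press / SST
  }
  adeq <- if (fit$MSE <= 0) Inf else
    (max(fit$fitted) - min(fit$fitted)) / sqrt(p * fit$MSE / n)
  structure(list(std_dev = sqrt(fit$MSE), mean = mean(t),
                 cv_pct = 100 * sqrt(fit$MSE) / mean(t),
                 r2 = r2, adj_r2 = adj, press = press, pred_r2 = pred,
                 adeq_precision = adeq, n = n, p = p),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf(
    "Std. dev. %.4g | Mean %.4g | CV%% %.4g | R2 %.4f | adj R2 %.4f | pred R2 %s | Adeq. precision %.4g\n",
    x$std_dev, x$mean, x$cv_pct, x$r2, x$adj_r2,
    ifelse(is.na(x$pred_r2), "NA", sprintf("%.4f", x$pred_r2)),
    x$adeq_precision))
  invisible(x)
}

#' Model adequacy flags
#'
#' The two conventional screening rules for response-surface models: the
#' adjusted and predicted \eqn{R^2} should agree within 0.2 (no overfitting)
#' and adequate precision should exceed 4 (signal well above noise).
#'
#' @param stats A [fit_stats] object.
#' @return List with `r2_gap` (adjusted minus predicted \eqn{R^2}),
#'   `r2_gap_ok`, `adeq_precision_ok`, and `pass` (both rules met).
#' @export
adequacy_check <- function(stats) {
  gap <- stats$adj_r2 - stats$pred_r2
  flag1 <- !is.na(gap) && gap < 0.2
  flag2 <- stats$adeq_precision > 4
  list(r2_gap = gap, r2_gap_ok = flag1, adeq_precision_ok = flag2,
       pass = flag1 && flag2)
}

#' Predict raw-scale responses from a fitted Scheffe model
#'
#' Evaluates the fitted polynomial at new compositions and back-transforms
#' to the raw response scale with [inverse_power]. For negative exponents
#' the transformed prediction must be positive; an out-of-domain composition
#' raises a classed error naming it.
#'
#' @param fit A [scheffe_fit].
#' @param newdata A [mixture_design], proportion matrix, or single
#'   composition.
#' @return Numeric vector of raw-scale predictions.
#' @examples
#' # encapsulation at the Spikevax-like hold-out composition
#' gt <- builtin_models()[["encapsulation_pct"]]
#' d <- builtin_design()
#' y <- predict_response(fit_scheffe(d, simulate_responses(d, seed = 1)$encapsulation_pct,
#'                                   gt$spec), c(0.10, 0.50, 0.385, 0.015))
#' @export
predict_response <- function(fit, newdata) {
  Xn <- scheffe_matrix(newdata, fit$spec)
  tpred <- drop(Xn %*% fit$coefficients)
  if ((fit$lambda < 0 || fit$lambda %% 1 != 0) && any(tpred <= 0)) {
    bad <- which(tpred <= 0)[1]
    mf_stop(paste0("out-of-domain prediction (transformed value <= 0) at composition (",
                   fmt_comp(design_matrix(newdata)[bad, ]), ")"),
            "mixformula_prediction_domain")
  }
  inverse_power(tpred, fit$lambda)
}

#' Hold-out validation of a fitted model
#'
#' Compares raw-scale predictions at hold-out compositions with their
#' observed responses. Refuses to validate on runs that were part of the
#' training design (same run id or identical composition): that would be
#' leakage, not validation.
#'
#' @param fit A [scheffe_fit].
#' @param holdout A [mixture_design] (typically the validation-flagged rows)
#'   or proportion matrix.
#' @param observed Observed raw-scale responses for the hold-out rows.
#' @return Data frame with `run_id`, `observed`, `predicted`, `abs_error`,
#'   `rel_error`.
#' @export
holdout_validation <- function(fit, holdout, observed) {
  hx <- design_matrix(holdout)
  ids <- if (inherits(holdout, "mixture_design")) holdout$run_ids
         else sprintf("H%02d", seq_len(nrow(hx)))
  if (any(ids %in% fit$run_ids))
    mf_stop(paste0("validation leakage: run(s) ",
                   paste(intersect(ids, fit$run_ids), collapse = ", "),
                   " were in the training design"),
            "mixformula_validation_leakage")
  for (i in seq_len(nrow(hx)))
    if (any(apply(fit$design, 1, function(r) max(abs(r - hx[i, ])) < 1e-12)))
      mf_stop(paste0("validation leakage: composition of ", ids[i],
                     " equals a training run"),
              "mixformula_validation_leakage")
  pred <- predict_response(fit, hx)
  data.frame(run_id = ids, observed = observed, predicted = pred,
             abs_error = abs(observed - pred),
             rel_error = abs(observed - pred) / abs(observed))
}
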