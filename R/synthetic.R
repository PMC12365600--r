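# Built-in reference design and response models plus synthetic response
# generation with the noise structure the analysis assumes (Gaussian on the
# transformed scale).

#' Built-in four-lipid reference design
#'
#' The 15-run I-optimal mixture design over DSPC, SM-102, cholesterol and
#' DMG-PEG2000 (runs M01--M15), plus the Spikevax-like composition MS
#' (10/50/38.5/1.5%) flagged as a validation run: MS is excluded from model
#' fitting and used only for hold-out comparison. Values are stored in
#' percent and converted to proportions.
#'
#' @return A [mixture_design] with [lnp_bounds] attached.
#' @examples
#' d <- builtin_design()
#' sum(!d$is_validation)   # 15 modeling runs
#' @export
builtin_design <- function() {
  pct <- matrix(c(
    19,   65,   15,   1,
    5,    35,   50,   10,
    18.3, 35.9, 35.8, 10,
    5,    53,   38,   4,
    40,   15,   35,   10,
    40,   29.5, 29.5, 1,
    14.9, 51.2, 26.2, 7.7,
    5,    65,   29,   1,
    23,   15,   58,   4,
    8.3,  65,   16.7, 10,
    40,   39.5, 15,   5.5,
    5,    20,   65,   10,
    29.9, 40.7, 26.2, 3.2,
    5,    29,   65,   1,
    24.7, 26.2, 45.9, 3.2,
    10,   50,   38.5, 1.5), ncol = 4, byrow = TRUE)
  b <- lnp_bounds()
  colnames(pct) <- b$names
  mixture_design(pct,
                 run_ids = c(sprintf("M%02d", 1:15), "MS"),
                 is_validation = c(rep(FALSE, 15), TRUE),
                 bounds = b)
}

new_ground_truth <- function(response, lambda, sigma, terms, beta, names) {
  spec <- scheffe_spec(4, terms, names = names)
  if (length(beta) != n_terms(spec))
    mf_stop("coefficient/term mismatch", "mixformula_spec_error")
  structure(list(response = response, lambda = lambda, sigma = sigma,
                 spec = spec,
                 beta = stats::setNames(beta, spec$labels)),
            class = "ground_truth")
}

#' Built-in fitted response models (ground truth for simulation)
#'
#' The three fitted Scheffe models of the four-lipid system, on their
#' power-transformed scales, with residual standard deviations on those
#' scales:
#' \itemize{
#'   \item encapsulation efficiency (%), lambda 1, sigma 14.31:
#'     `57.77 A + 62.05 B + 106.35 C - 177.89 D`
#'   \item particle diameter (nm), lambda 0.5, sigma 1.56:
#'     `25.87 A + 9.12 B + 4.22 C - 77.48 D - 21.14 AB + 12.29 BC
#'      + 49.40 BD + 117.57 CD`
#'   \item nMFI, lambda -1.5, sigma 0.0961:
#'     `-0.15 A + 0.30 B + 0.45 C + 5.61 D + 1.67 AC`
#' }
#' with A = DSPC, B = SM-102, C = cholesterol, D = DMG-PEG2000 as
#' proportions.
#'
#' @return Named list of `ground_truth` records
#'   (`encapsulation_pct`, `diameter_nm`, `nmfi`), each with fields
#'   `response`, `lambda`, `sigma`, `spec`, `beta`.
#' @export
builtin_models <- function() {
  nm <- lnp_bounds()$names
  list(
    encapsulation_pct = new_ground_truth(
      "encapsulation_pct", lambda = 1, sigma = 14.31,
      terms = list(1, 2, 3, 4),
      beta = c(57.77, 62.05, 106.35, -177.89), names = nm),
    diameter_nm = new_ground_truth(
      "diameter_nm", lambda = 0.5, sigma = 1.56,
      terms = list(1, 2, 3, 4, c(1, 2), c(2, 3), c(2, 4), c(3, 4)),
      beta = c(25.87, 9.12, 4.22, -77.48, -21.14, 12.29, 49.40, 117.57),
      names = nm),
    nmfi = new_ground_truth(
      "nmfi", lambda = -1.5, sigma = 0.0961,
      terms = list(1, 2, 3, 4, c(1, 3)),
      beta = c(-0.15, 0.30, 0.45, 5.61, 1.67), names = nm))
}

# raw-scale validity window per response
response_ok <- function(response, traw, t, lambda) {
  ok <- is.finite(t)
  if (lambda < 0 || lambda %% 1 != 0) ok <- ok & t > 0
  if (response == "encapsulation_pct") ok & traw > 0 & traw <= 100
  else ok & traw > 0
}

#' Simulate synthetic response tables from ground-truth models
#'
#' Draws responses at the design compositions as
#' \eqn{t = X\beta + \varepsilon}, \eqn{\varepsilon \sim N(0, \sigma^2)} on
#' the transformed scale, then back-transforms. Draws falling outside the
#' valid raw window (encapsulation outside (0, 100]; non-positive diameter
#' or nMFI; non-positive transformed values under a negative exponent) are
#' redrawn, making the marginals truncated normal on the transformed scale;
#' redraw counts are recorded in the `"redraws"` attribute. Output is
#' deterministic given the seed.
#'
#' @param design A [mixture_design] (responses are generated for every row,
#'   including validation rows).
#' @param truth List of `ground_truth` records (default [builtin_models()]).
#' @param seed Optional integer seed.
#' @param n_rep Replicate tables per run (default 1); with `n_rep > 1` a
#'   `rep` column distinguishes replicates.
#' @param sigma Optional named numeric overriding each record's sigma (a 0
#'   yields noiseless responses).
#' @return Data frame with `run_id` (and `rep` if `n_rep > 1`) plus one
#'   column per response; attribute `redraws` (named counts).
#' @examples
#' simulate_responses(builtin_design(), seed = 1)
#' @export
simulate_responses <- function(design, truth = builtin_models(), seed = NULL,
                               n_rep = 1, sigma = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- design_matrix(design)
  ids <- if (inherits(design, "mixture_design")) design$run_ids
         else sprintf("R%02d", seq_len(nrow(x)))
  n <- nrow(x)
  out <- data.frame(run_id = rep(ids, n_rep))
  if (n_rep > 1) out$rep <- rep(seq_len(n_rep), each = n)
  redraws <- stats::setNames(integer(length(truth)),
                             vapply(truth, `[[`, "", "response"))
  for (gt in truth) {
    sg <- if (!is.null(sigma) && gt$response %in% names(sigma))
      sigma[[gt$response]] else gt$sigma
    mu <- rep(drop(scheffe_matrix(x, gt$spec) %*% gt$beta), n_rep)
    t <- mu + stats::rnorm(length(mu), 0, sg)
    raw <- suppressWarnings(t^(1 / gt$lambda))
    if (gt$lambda == 0) raw <- exp(t)
    bad <- !response_ok(gt$response, raw, t, gt$lambda)
    tries <- 0
    while (any(bad)) {
      tries <- tries + 1
      redraws[gt$response] <- redraws[gt$response] + sum(bad)
      if (redraws[gt$response] > 0.5 * length(mu) * max(tries, 20))
        mf_stop(paste0("systematic infeasibility simulating ", gt$response,
                       " (>50% redraws)"), "mixformula_generation_error")
      t[bad] <- mu[bad] + stats::rnorm(sum(bad), 0, sg)
      raw[bad] <- if (gt$lambda == 0) exp(t[bad]) else
        suppressWarnings(t[bad]^(1 / gt$lambda))
      bad <- !response_ok(gt$response, raw, t, gt$lambda)
    }
    out[[gt$response]] <- raw
  }
  attr(out, "redraws") <- redraws
  out
}

#' Simulate a positive response with a known Box-Cox exponent
#'
#' Fixture generator for transform-recovery checks: draws
#' \eqn{t = X\beta + \varepsilon} on the transformed scale and returns
#' \eqn{y = t^{1/\lambda}} (\eqn{e^t} at 0), redrawing values whose inverse
#' is undefined or non-positive. Used to test that [boxcox_scan] confidence
#' intervals cover the generating exponent.
#'
#' @param lambda_true Generating exponent.
#' @param beta Coefficients for `spec`.
#' @param sigma Noise SD on the transformed scale.
#' @param design A [mixture_design] or proportion matrix.
#' @param spec A [scheffe_spec].
#' @param seed Optional integer seed.
#' @return Positive numeric response vector.
#' @export
simulate_boxcox_dataset <- function(lambda_true, beta, sigma, design, spec,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- design_matrix(design)
  mu <- drop(scheffe_matrix(x, spec) %*% beta)
  t <- mu + stats::rnorm(length(mu), 0, sigma)
  invertible <- function(t) {
    if (lambda_true == 0) rep(TRUE, length(t)) else t > 0
  }
  bad <- !invertible(t)
  total_bad <- sum(bad); tries <- 0
  while (any(bad)) {
    tries <- tries + 1
    if (total_bad > 0.5 * length(mu) * max(tries, 20))
      mf_stop("systematic infeasibility in Box-Cox fixture (>50% redraws)",
              "mixformula_generation_error")
    t[bad] <- mu[bad] + stats::rnorm(sum(bad), 0, sigma)
    bad <- !invertible(t)
    total_bad <- total_bad + sum(bad)
  }
  if (lambda_true == 0) exp(t) else t^(1 / lambda_true)
}
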