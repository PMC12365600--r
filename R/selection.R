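# Term screening by sequential (type-I) SS and model selection by BIC
# stepwise search with mixture-hierarchy protection (linear blending terms
# are mandatory and never removed).

# SSE and rank of the Scheffe fit on the training rows for a term list;
# an intercept column can be prepended (used by sequential_ss so that the
# empty model is the mean and type-I SS telescopes to the corrected SST)
sse_for_terms <- function(x, t, spec_q, terms, intercept = FALSE) {
  if (length(terms) == 0) {
    X <- if (intercept) matrix(1, length(t), 1) else NULL
    if (is.null(X)) return(list(sse = sum(t^2), rank = 0L))
  } else {
    sp <- scheffe_spec(spec_q, terms)
    X <- scheffe_matrix(x, sp)
    if (intercept) X <- cbind(1, X)
  }
  f <- stats::lm.fit(X, t)
  list(sse = sum(f$residuals^2), rank = f$rank)
}

training_parts <- function(design, y, lambda) {
  x <- design_matrix(design)
  train <- if (inherits(design, "mixture_design")) !design$is_validation
           else rep(TRUE, nrow(x))
  list(x = x[train, , drop = FALSE],
       t = power_transform(y[train], lambda))
}

term_label <- function(term, names) paste(names[term], collapse = ":")

#' Sequential (type-I) sum-of-squares table
#'
#' Adds terms one at a time in the stated order and attributes to each the
#' incremental reduction in SSE, starting from the intercept-only (mean)
#' model so that the increments plus the final SSE telescope exactly to the
#' mean-corrected total sum of squares. Each increment is F-tested against
#' the final model's mean square error (descriptive, no multiplicity
#' correction). A term adding no rank (collinear with its predecessors) is
#' reported as a zero-df step rather than an error.
#'
#' @param design A [mixture_design].
#' @param y Raw-scale response vector aligned with the design.
#' @param ordered_terms A [scheffe_spec] (its term order is the entry order)
#'   or a list of terms.
#' @param lambda Power exponent of the modeling scale.
#' @return Object of class `sequential_ss`: `table` (term, df, ss, f,
#'   p_value), `sse_final`, `df_resid`, `sst`.
#' @export
sequential_ss <- function(design, y, ordered_terms, lambda = 1) {
  spec <- if (inherits(ordered_terms, "scheffe_spec")) ordered_terms
          else scheffe_spec(ncol(design_matrix(design)), ordered_terms)
  tp <- training_parts(design, y, lambda)
  n <- length(tp$t)
  sst <- sum((tp$t - mean(tp$t))^2)
  k <- length(spec$terms)
  sse <- numeric(k + 1); rk <- integer(k + 1)
  sse[1] <- sst; rk[1] <- 1L   # intercept-only base
  for (i in seq_len(k)) {
    f <- sse_for_terms(tp$x, tp$t, spec$q, spec$terms[seq_len(i)],
                       intercept = TRUE)
    sse[i + 1] <- f$sse; rk[i + 1] <- f$rank
  }
  ss <- sse[-(k + 1)] - sse[-1]
  df <- diff(rk)
  df_resid <- n - rk[k + 1]
  if (df_resid <= 0)
    mf_stop("saturated model: no residual degrees of freedom",
            "mixformula_underdetermined")
  mse <- sse[k + 1] / df_resid
  fstat <- ifelse(df > 0, (ss / pmax(df, 1)) / mse, NA_real_)
  pval <- ifelse(df > 0, stats::pf(fstat, df, df_resid, lower.tail = FALSE),
                 NA_real_)
  structure(list(
    table = data.frame(term = spec$labels, df = df, ss = ss, f = fstat,
                       p_value = pval),
    sse_final = sse[k + 1], df_resid = df_resid, sst = sst),
    class = "sequential_ss")
}

#' @export
print.sequential_ss <- function(x, ...) {
  cat("Sequential (type-I) sums of squares\n")
  print(x$table, digits = 4)
  cat(sprintf("Residual SSE %.4g on %d df (SST %.4g)\n",
              x$sse_final, x$df_resid, x$sst))
  invisible(x)
}

#' Bayesian information criterion for a Gaussian least-squares fit
#'
#' Profile-Gaussian form with constants dropped:
#' `BIC = n * log(SSE/n) + k * log(n)`, `k` the number of fitted
#' coefficients. Smaller is better; adding a useless term (same SSE) costs
#' `log(n)`.
#'
#' @param n Number of observations.
#' @param SSE Residual sum of squares (> 0; a perfect fit returns `-Inf`
#'   with a warning).
#' @param k Number of coefficients.
#' @return Scalar BIC.
#' @examples
#' bic_score(8, 8, 2)   # 2 * log(8)
#' @export
bic_score <- function(n, SSE, k) {
  if (n <= 0) mf_stop("n must be positive", "mixformula_domain_error")
  if (SSE < 0) mf_stop("SSE must be non-negative", "mixformula_domain_error")
  if (SSE == 0) {
    mf_warn("perfect fit (SSE = 0): BIC is -Inf", "mixformula_perfect_fit")
    return(-Inf)
  }
  n * log(SSE / n) + k * log(n)
}

default_mandatory <- function(q) as.list(seq_len(q))

stepwise_engine <- function(design, y, lambda, candidate_terms,
                            mandatory_terms, direction) {
  q <- ncol(design_matrix(design))
  if (is.null(mandatory_terms)) mandatory_terms <- default_mandatory(q)
  mandatory_terms <- lapply(mandatory_terms, function(t) sort(as.integer(t)))
  candidate_terms <- lapply(candidate_terms, function(t) sort(as.integer(t)))
  key <- function(ts) vapply(ts, paste, "", collapse = ":")
  candidate_terms <- candidate_terms[!key(candidate_terms) %in%
                                       key(mandatory_terms)]
  tp <- training_parts(design, y, lambda)
  n <- length(tp$t)
  cnames <- colnames(tp$x)
  if (is.null(cnames)) cnames <- paste0("x", seq_len(q))

  # SSE below float noise (relative 1e-16) is a perfect fit: BIC -Inf,
  # so parsimony alone decides among exactly-fitting models
  snap <- 1e-16 * sum(tp$t^2)
  bic_of <- function(terms) {
    f <- sse_for_terms(tp$x, tp$t, q, terms)
    if (n <= f$rank) return(list(bic = Inf, sse = NA_real_, k = f$rank))
    sse <- if (f$sse <= snap) 0 else f$sse
    list(bic = suppressWarnings(bic_score(n, sse, f$rank)),
         sse = f$sse, k = f$rank)
  }

  current <- if (direction == "forward") mandatory_terms
             else unique(c(mandatory_terms, candidate_terms))
  cur <- bic_of(current)
  if (!is.finite(cur$bic) && is.na(cur$sse))
    mf_stop(if (direction == "backward")
              "full model under-determined (n <= p); use forward selection"
            else "under-determined starting model",
            "mixformula_underdetermined")
  steps <- data.frame(step = 0L, action = "start",
                      term = NA_character_, sse = cur$sse, k = cur$k,
                      bic = cur$bic)
  repeat {
    if (direction == "forward") {
      pool <- candidate_terms[!key(candidate_terms) %in% key(current)]
      trials <- lapply(pool, function(t) c(current, list(t)))
    } else {
      pool <- current[!key(current) %in% key(mandatory_terms)]
      trials <- lapply(seq_along(pool), function(i) {
        current[key(current) != key(pool)[i]]
      })
    }
    if (length(pool) == 0) break
    scores <- vapply(trials, function(ts) bic_of(ts)$bic, numeric(1))
    best <- which.min(scores)   # ties: first (lowest candidate index)
    accept <- if (direction == "forward")
      scores[best] < cur$bic - 1e-12         # strict improvement to add
    else
      scores[best] <= cur$bic + 1e-12        # equal BIC: prefer fewer terms
    if (scores[best] == Inf || !accept) break
    current <- trials[[best]]
    cur <- bic_of(current)
    steps <- rbind(steps, data.frame(
      step = nrow(steps), action = if (direction == "forward") "add"
                                   else "remove",
      term = term_label(pool[[best]], cnames),
      sse = cur$sse, k = cur$k, bic = cur$bic))
  }
  structure(list(steps = steps, direction = direction,
                 final_spec = scheffe_spec(q, current, names = cnames),
                 bic = cur$bic),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("BIC", x$direction, "selection trace\n")
  print(x$steps, digits = 5)
  cat("Final model:", paste(x$final_spec$labels, collapse = " + "),
      sprintf("(BIC %.4f)\n", x$bic))
  invisible(x)
}

#' BIC forward selection of Scheffe terms
#'
#' Starts from the mandatory terms (default: all linear blending terms,
#' which keeps every model mixture-hierarchy valid) and repeatedly adds the
#' candidate term giving the largest BIC decrease, stopping when no addition
#' decreases BIC.
#'
#' @param design A [mixture_design].
#' @param y Raw-scale response vector.
#' @param candidate_terms List of candidate terms (integer vectors, usually
#'   pairs).
#' @param mandatory_terms Terms always kept (default all `q` singletons).
#' @param lambda Power exponent of the modeling scale.
#' @return A `selection_trace`: `steps` data frame (BIC non-increasing over
#'   accepted moves), `final_spec`, `bic`, `direction`.
#' @export
forward_select <- function(design, y, candidate_terms,
                           mandatory_terms = NULL, lambda = 1) {
  stepwise_engine(design, y, lambda, candidate_terms, mandatory_terms,
                  "forward")
}

#' BIC backward elimination of Scheffe terms
#'
#' Starts from the full candidate model (mandatory plus all candidate
#' terms) and repeatedly removes the non-mandatory term whose removal most
#' decreases BIC, stopping when no removal improves. Errors with advice to
#' use forward selection when the full model is under-determined (e.g. a
#' four-component full quadratic has 10 terms against 15 runs, but richer
#' candidate sets may exceed n).
#'
#' @inheritParams forward_select
#' @param full_terms Candidate terms forming, with the mandatory set, the
#'   initial full model.
#' @return A `selection_trace`.
#' @export
backward_eliminate <- function(design, y, full_terms,
                               mandatory_terms = NULL, lambda = 1) {
  stepwise_engine(design, y, lambda, full_terms, mandatory_terms, "backward")
}

#' Exhaustive best-subset search (selection oracle)
#'
#' Enumerates every hierarchy-valid subset (mandatory terms plus any subset
#' of the candidates) and returns the BIC minimizer. Ties break to fewer
#' terms, then lexicographic term order. Intended as the reference the
#' stepwise searches are measured against; limited to 2^20 subsets.
#'
#' @inheritParams forward_select
#' @param max_terms Optional cap on the total number of terms.
#' @return List with `spec` (the best [scheffe_spec]) and `bic`.
#' @export
exhaustive_best_subset <- function(design, y, candidate_terms,
                                   mandatory_terms = NULL, lambda = 1,
                                   max_terms = Inf) {
  q <- ncol(design_matrix(design))
  if (is.null(mandatory_terms)) mandatory_terms <- default_mandatory(q)
  mandatory_terms <- lapply(mandatory_terms, function(t) sort(as.integer(t)))
  candidate_terms <- lapply(candidate_terms, function(t) sort(as.integer(t)))
  key <- function(ts) vapply(ts, paste, "", collapse = ":")
  candidate_terms <- candidate_terms[!key(candidate_terms) %in%
                                       key(mandatory_terms)]
  m <- length(candidate_terms)
  if (2^m > 2^20)
    mf_stop("more than 2^20 candidate subsets", "mixformula_size_error")
  tp <- training_parts(design, y, lambda)
  n <- length(tp$t)
  cnames <- colnames(tp$x)
  snap <- 1e-16 * sum(tp$t^2)
  best <- NULL
  for (mask in 0:(2^m - 1)) {
    sel <- candidate_terms[bitwAnd(bitwShiftR(mask, 0:max(m - 1, 0)), 1L) == 1L]
    if (m == 0) sel <- list()
    terms <- c(mandatory_terms, sel)
    if (length(terms) > max_terms) next
    f <- sse_for_terms(tp$x, tp$t, q, terms)
    if (n <= f$rank) next
    sse <- if (f$sse <= snap) 0 else f$sse
    bic <- suppressWarnings(bic_score(n, sse, f$rank))
    lex <- paste(vapply(terms, paste, "", collapse = ":"), collapse = "|")
    diff <- bic - if (is.null(best)) Inf else best$bic   # NaN if both -Inf
    tie <- !is.null(best) && (is.nan(diff) || abs(diff) <= 1e-12)
    if (is.null(best) || (!is.nan(diff) && diff < -1e-12) ||
        (tie && (length(terms) < best$nt ||
                 (length(terms) == best$nt && lex < best$lex)))) {
      best <- list(terms = terms, bic = bic, nt = length(terms), lex = lex)
    }
  }
  if (is.null(best))
    mf_stop("no estimable subset found", "mixformula_underdetermined")
  list(spec = scheffe_spec(q, best$terms, names = cnames), bic = best$bic)
}

#' Run both stepwise directions and arbitrate by BIC
#'
#' Runs forward selection and backward elimination and returns the trace
#' with the lower final BIC (exact ties favor the model with fewer terms,
#' then the forward result).
#'
#' @inheritParams forward_select
#' @return The winning `selection_trace`, with the losing direction attached
#'   as attribute `"other"`.
#' @export
stepwise_select <- function(design, y, candidate_terms,
                            mandatory_terms = NULL, lambda = 1) {
  fw <- forward_select(design, y, candidate_terms, mandatory_terms, lambda)
  bw <- tryCatch(
    backward_eliminate(design, y, candidate_terms, mandatory_terms, lambda),
    mixformula_underdetermined = function(e) NULL)
  if (is.null(bw)) return(fw)
  pick <- if (bw$bic < fw$bic - 1e-12) bw
          else if (fw$bic < bw$bic - 1e-12) fw
          else if (n_terms(bw$final_spec) < n_terms(fw$final_spec)) bw
          else fw
  attr(pick, "other") <- if (identical(pick, fw)) bw else fw
  pick
}
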