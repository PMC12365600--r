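# Design optimality: moment matrix, I/D criteria, point exchange.

#' Region moment matrix for the I-criterion
#'
#' Monte-Carlo estimate of \eqn{M = E[f(x) f(x)^T]} over the uniform
#' distribution on the bounded simplex region, where \eqn{f} is the Scheffe
#' model expansion. The I-criterion (average prediction variance) of a design
#' is `trace(solve(XtX), M)`; M carries the region geometry.
#'
#' @param bounds A [component_bounds].
#' @param spec A [scheffe_spec].
#' @param n_mc Number of Monte-Carlo points (>= 1000).
#' @param seed Optional integer seed.
#' @return A symmetric positive semidefinite p x p matrix.
#' @examples
#' b <- component_bounds(c("a", "b"), c(0, 0), c(1, 1))
#' moment_matrix(b, scheffe_spec(2, "linear"), n_mc = 2000, seed = 1)
#' @export
moment_matrix <- function(bounds, spec, n_mc = 10000, seed = NULL) {
  if (n_mc < 1000) mf_stop("n_mc must be >= 1000", "mixformula_domain_error")
  if (!is.null(seed)) set.seed(seed)
  pts <- sample_region(bounds, n_mc)
  X <- scheffe_matrix(pts, spec)
  M <- crossprod(X) / n_mc
  (M + t(M)) / 2
}

info_inverse <- function(design, spec) {
  X <- scheffe_matrix(design, spec)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p)
    mf_stop(paste0("singular information matrix; deficient term set: ",
                   paste(spec$labels, collapse = ", ")),
            "mixformula_singular_information")
  chol2inv(qr.R(qrX)[seq_len(p), seq_len(p), drop = FALSE])
}

#' Design optimality criterion
#'
#' Evaluates a design under the I- or D-criterion for a Scheffe model. Both
#' are oriented for minimization: `I = trace(solve(X'X) %*% M)` (average
#' prediction variance over the region) and `D = -log det(X'X)`.
#'
#' @param design A [mixture_design] or proportion matrix.
#' @param spec A [scheffe_spec].
#' @param which `"I"` or `"D"`.
#' @param M Region moment matrix (required for `which = "I"`), from
#'   [moment_matrix].
#' @return Scalar criterion value (smaller is better).
#' @export
design_criterion <- function(design, spec, which = c("I", "D"), M = NULL) {
  which <- match.arg(which)
  X <- scheffe_matrix(design, spec)
  if (nrow(X) < ncol(X))
    mf_stop("fewer runs than model terms", "mixformula_underdetermined")
  if (which == "D") {
    XtX <- crossprod(X)
    if (qr(X)$rank < ncol(X))
      mf_stop(paste0("singular information matrix; deficient term set: ",
                     paste(spec$labels, collapse = ", ")),
              "mixformula_singular_information")
    return(-as.numeric(determinant(XtX, logarithm = TRUE)$modulus))
  }
  if (is.null(M) || !all(dim(M) == n_terms(spec)))
    mf_stop("I-criterion needs a moment matrix of matching dimension",
            "mixformula_domain_error")
  inv <- info_inverse(design, spec)
  sum(inv * M)   # trace(inv %*% M), both symmetric
}

#' Pointwise prediction variance
#'
#' Unit-variance-scaled prediction variance \eqn{f(x)^T (X^TX)^{-1} f(x)} of
#' a Scheffe model at composition `x` under a given design. Its average over
#' uniform region points converges to the I-criterion.
#'
#' @param design A [mixture_design] or proportion matrix.
#' @param spec A [scheffe_spec].
#' @param x A composition (proportion vector or one-row matrix).
#' @return Non-negative scalar.
#' @export
prediction_variance <- function(design, spec, x) {
  inv <- info_inverse(design, spec)
  f <- drop(scheffe_matrix(rbind(x), spec))
  as.numeric(f %*% inv %*% f)
}

criterion_or_inf <- function(x, spec, which, M) {
  tryCatch(design_criterion(x, spec, which, M),
           mixformula_singular_information = function(e) Inf)
}

#' Optimal design by Fedorov point exchange
#'
#' Searches for an I- or D-optimal exact design of `n_runs` points over a
#' candidate set: from each random start, every design point is tested
#' against every candidate and the swap yielding the largest criterion
#' decrease is accepted, until no swap improves by more than `rel_tol`
#' relative. The best design across starts is returned. Ties between equal
#' swaps resolve to the lowest candidate index, so results are deterministic
#' given the seed.
#'
#' @param bounds A [component_bounds].
#' @param spec A [scheffe_spec].
#' @param n_runs Number of design runs (>= number of model terms).
#' @param which `"I"` or `"D"`.
#' @param candidates Optional candidate [mixture_design]; default
#'   [build_candidate_set] with `10 * q` interior points.
#' @param n_starts Number of random starts (default 5).
#' @param seed Optional integer seed (drives starts and, if needed,
#'   candidate and moment-matrix sampling).
#' @param M Moment matrix for the I-criterion; computed from `bounds` when
#'   absent.
#' @param n_mc Monte-Carlo size for an internally computed moment matrix.
#' @param rel_tol Relative improvement threshold to keep exchanging.
#' @param max_passes Safety cap on full exchange passes per start.
#' @return List with `design` (a [mixture_design], run ids `D01`...) and
#'   `report` (class `optimality_report`: criterion name and value, accepted
#'   swaps, per-start initial and final values, best start index).
#' @export
exchange_design <- function(bounds, spec, n_runs, which = c("I", "D"),
                            candidates = NULL, n_starts = 5, seed = NULL,
                            M = NULL, n_mc = 10000, rel_tol = 1e-8,
                            max_passes = 200) {
  which <- match.arg(which)
  if (!is.null(seed)) set.seed(seed)
  p <- n_terms(spec)
  if (n_runs < p)
    mf_stop("n_runs must be >= number of model terms",
            "mixformula_underdetermined")
  if (is.null(candidates))
    candidates <- build_candidate_set(bounds, n_interior = 10 * spec$q)
  cx <- design_matrix(candidates)
  m <- nrow(cx)
  if (m == 0) mf_stop("empty candidate set", "mixformula_domain_error")
  if (which == "I" && is.null(M)) M <- moment_matrix(bounds, spec, n_mc)

  best <- NULL
  start_init <- start_final <- rep(NA_real_, n_starts)
  total_swaps <- 0
  for (s in seq_len(n_starts)) {
    idx <- sample.int(m, n_runs, replace = n_runs > m)
    crit <- criterion_or_inf(cx[idx, , drop = FALSE], spec, which, M)
    tries <- 0
    while (!is.finite(crit) && tries < 20) {
      idx <- sample.int(m, n_runs, replace = n_runs > m)
      crit <- criterion_or_inf(cx[idx, , drop = FALSE], spec, which, M)
      tries <- tries + 1
    }
    start_init[s] <- crit
    if (!is.finite(crit)) { start_final[s] <- Inf; next }
    for (pass in seq_len(max_passes)) {
      best_gain <- 0; best_i <- 0L; best_j <- 0L; best_val <- crit
      for (i in seq_len(n_runs)) {
        for (j in seq_len(m)) {
          if (idx[i] == j) next
          trial <- idx; trial[i] <- j
          val <- criterion_or_inf(cx[trial, , drop = FALSE], spec, which, M)
          gain <- crit - val
          if (is.finite(val) && gain > best_gain + 1e-15) {
            best_gain <- gain; best_i <- i; best_j <- j; best_val <- val
          }
        }
      }
      if (best_i == 0L || best_gain <= rel_tol * max(1, abs(crit))) break
      idx[best_i] <- best_j
      crit <- best_val
      total_swaps <- total_swaps + 1
    }
    start_final[s] <- crit
    if (is.null(best) || crit < best$crit) best <- list(idx = idx, crit = crit)
  }
  if (is.null(best))
    mf_stop("all starts produced singular designs",
            "mixformula_singular_information")
  des <- mixture_design(cx[best$idx, , drop = FALSE],
                        run_ids = sprintf("D%02d", seq_len(n_runs)),
                        bounds = bounds)
  report <- structure(
    list(criterion = which, value = best$crit, swaps = total_swaps,
         n_starts = n_starts, best_start = which.min(start_final),
         start_initial = start_init, start_final = start_final),
    class = "optimality_report")
  list(design = des, report = report)
}

#' @export
print.optimality_report <- function(x, ...) {
  cat(sprintf("%s-optimal exchange: value %.6g after %d swaps (%d starts, best #%d)\n",
              x$criterion, x$value, x$swaps, x$n_starts, x$best_start))
  invisible(x)
}
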