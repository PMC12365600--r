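# Candidate-point generation on the bounded simplex.

# uniform sampling of the bounded simplex region by rejection from the
# unconstrained simplex (flat Dirichlet); errors if acceptance < min_rate
sample_region <- function(bounds, n, min_rate = 1e-4) {
  q <- length(bounds$names)
  got <- matrix(numeric(0), ncol = q)
  tried <- 0
  batch <- max(1000L, as.integer(4 * n))
  while (nrow(got) < n) {
    e <- matrix(stats::rexp(batch * q), ncol = q)
    pts <- e / rowSums(e)
    keep <- in_bounds(pts, bounds)
    got <- rbind(got, pts[keep, , drop = FALSE])
    tried <- tried + batch
    if (tried >= max(1e5, n / min_rate) && nrow(got) / tried < min_rate)
      mf_stop(sprintf(
        "rejection acceptance rate %.2e below %.0e; bounds too tight for simplex rejection sampling, consider more permissive bounds",
        nrow(got) / tried, min_rate), "mixformula_sampling_failure")
  }
  colnames(got) <- bounds$names
  got[seq_len(n), , drop = FALSE]
}

# extreme vertices of the bounded simplex: fix q-1 components at bound
# combinations, solve the remaining (fill) component, keep feasible points
region_vertices <- function(bounds, tol = 1e-9) {
  q <- length(bounds$names)
  verts <- list()
  for (fill in seq_len(q)) {
    others <- setdiff(seq_len(q), fill)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), q - 1))
    for (k in seq_len(nrow(combos))) {
      v <- numeric(q)
      at_up <- as.logical(combos[k, ])
      v[others] <- ifelse(at_up, bounds$upper[others], bounds$lower[others])
      v[fill] <- 1 - sum(v[others])
      if (v[fill] >= bounds$lower[fill] - tol &&
          v[fill] <= bounds$upper[fill] + tol) {
        v[fill] <- min(max(v[fill], bounds$lower[fill]), bounds$upper[fill])
        verts[[length(verts) + 1]] <- v
      }
    }
  }
  if (length(verts) == 0)
    mf_stop("no feasible vertices: empty mixture region",
            "mixformula_region_empty")
  V <- unique(round(do.call(rbind, verts), 10))
  colnames(V) <- bounds$names
  V
}

#' Build a candidate set for design optimization
#'
#' Standard candidate geometry for exchange algorithms on a bounded mixture
#' simplex: the extreme vertices of the region, the midpoints of every
#' vertex pair (edge centroids), the overall centroid, and optionally
#' uniform interior points obtained by rejection sampling from the
#' unconstrained simplex.
#'
#' @param bounds A [component_bounds].
#' @param n_interior Number of uniform interior points to add (default 0).
#' @param seed Optional integer seed for the interior sampling.
#' @return A [mixture_design] of deduplicated candidates (run ids
#'   `C0001`, ...) with `bounds` attached.
#' @examples
#' b <- component_bounds(c("a", "b", "c"), c(0, 0, 0), c(1, 1, 1))
#' build_candidate_set(b)       # 3 vertices + 3 edge midpoints + centroid
#' @export
build_candidate_set <- function(bounds, n_interior = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- region_vertices(bounds)
  pts <- V
  if (nrow(V) >= 2) {
    prs <- utils::combn(nrow(V), 2)
    mids <- (V[prs[1, ], , drop = FALSE] + V[prs[2, ], , drop = FALSE]) / 2
    pts <- rbind(pts, mids)
  }
  pts <- rbind(pts, colMeans(V))
  if (n_interior > 0) pts <- rbind(pts, sample_region(bounds, n_interior))
  pts <- unique(round(pts, 10))
  pts <- renormalize_rows(pts)
  mixture_design(pts, run_ids = sprintf("C%04d", seq_len(nrow(pts))),
                 bounds = bounds)
}
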