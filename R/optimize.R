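# Multi-response formulation optimization by weighted desirability over the
# constrained simplex with optional fixed components.

# exact projection-style repair onto {sum(s) = total, lo <= s <= up} by
# bisection on a common shift: s_i = clamp(v_i + tau, lo_i, up_i)
project_bounded_simplex <- function(v, lo, up, total = 1) {
  g <- function(tau) sum(pmin(pmax(v + tau, lo), up)) - total
  a <- -2; b <- 2
  while (g(a) > 0) a <- a * 2
  while (g(b) < 0) b <- b * 2
  for (i in 1:200) {
    mid <- (a + b) / 2
    if (g(mid) > 0) b <- mid else a <- mid
  }
  pmin(pmax(v + (a + b) / 2, lo), up)
}

#' Optimize a formulation against multiple fitted responses
#'
#' Searches the constrained mixture simplex for compositions maximizing the
#' importance-weighted overall desirability of raw-scale predictions from a
#' set of fitted Scheffe models. Components may be held fixed (e.g. the
#' ionizable lipid at 0.65 and the PEG-lipid at 0.01); the free components
#' then live on a rescaled sub-simplex. The search seeds from the candidate
#' geometry of the free region (vertices, edge centroids, centroid, interior
#' samples), refines the best seeds by Nelder-Mead with an exact
#' bound-feasibility repair inside the objective, and returns distinct local
#' optima ranked by desirability. Because desirability is evaluated on the
#' raw scale, a negative transform exponent cannot flip a goal's direction.
#'
#' @param models Named list of [scheffe_fit] objects; names are response
#'   names referenced by the goals.
#' @param goals List of [goal()] objects (each `goal$response` must name a
#'   model).
#' @param bounds A [component_bounds] over all components.
#' @param fixed Optional named numeric of fixed component proportions
#'   (consistent with bounds, `sum(fixed) < 1`).
#' @param n_starts Number of seeds refined by local search (default 50).
#' @param n_top Number of ranked candidates returned (default 5).
#' @param seed Optional integer seed.
#' @return Object of class `optimization_result`: `candidates` data frame
#'   (composition columns, predicted responses `pred_<response>`, per-goal
#'   desirabilities `d_<response>`, overall `D`, sorted by `D` descending),
#'   plus `goals`, `fixed`, `n_starts`, `seed`. Warns (classed
#'   `mixformula_empty_result`) when the best achievable desirability is 0.
#' @export
optimize_formulation <- function(models, goals, bounds, fixed = NULL,
                                 n_starts = 50, n_top = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(models)) || any(names(models) == ""))
    mf_stop("'models' must be a named list", "mixformula_goal_error")
  for (g in goals)
    if (!g$response %in% names(models))
      mf_stop(paste0("goal response '", g$response, "' has no fitted model"),
              "mixformula_goal_error")
  comp <- bounds$names
  q <- length(comp)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% comp))
      mf_stop("fixed components must be named after bounds components",
              "mixformula_infeasible")
    if (any(fixed < bounds$lower[names(fixed)] - 1e-12) ||
        any(fixed > bounds$upper[names(fixed)] + 1e-12) || sum(fixed) >= 1)
      mf_stop("fixed components violate bounds or consume the mixture",
              "mixformula_infeasible")
  }
  free <- setdiff(comp, names(fixed))
  rfree <- 1 - sum(fixed %||% 0)
  k <- length(free)
  lo <- bounds$lower[free]; up <- bounds$upper[free]
  if (sum(lo) > rfree + 1e-12 || sum(up) < rfree - 1e-12)
    mf_stop("free components cannot absorb the non-fixed remainder",
            "mixformula_infeasible")

  expand <- function(sfree) {   # free proportions -> full composition row
    v <- stats::setNames(numeric(q), comp)
    v[free] <- sfree
    if (!is.null(fixed)) v[names(fixed)] <- fixed
    v
  }
  predict_all <- function(compv) {
    vapply(models, function(m) {
      tryCatch(predict_response(m, rbind(compv)),
               mixformula_prediction_domain = function(e) NA_real_)
    }, numeric(1))
  }
  dscore <- function(compv) {
    preds <- predict_all(compv)
    d <- vapply(goals, function(g) {
      p <- preds[[g$response]]
      if (is.na(p)) 0 else desirability_value(p, g)
    }, numeric(1))
    r <- vapply(goals, `[[`, 1L, "importance")
    list(D = overall_desirability(pmin(pmax(d, 0), 1), r), d = d,
         preds = preds)
  }

  # seed candidates on the free sub-simplex (scaled to sum 1)
  slo <- pmax(lo / rfree, 0); sup <- pmin(up / rfree, 1)
  if (k == 1) {
    seeds <- matrix(rfree, 1, 1, dimnames = list(NULL, free))
  } else {
    sub <- component_bounds(free, slo, sup)
    seeds <- design_matrix(build_candidate_set(sub,
                                               n_interior = max(50, 10 * k)))
    seeds <- seeds * rfree
  }
  seedD <- apply(seeds, 1, function(s) dscore(expand(s))$D)

  results <- list(add = function(s) NULL)
  pool <- list()
  add_point <- function(sfree) {
    sc <- dscore(expand(sfree))
    pool[[length(pool) + 1]] <<- c(list(sfree = sfree), sc)
  }
  for (i in seq_len(nrow(seeds))) add_point(seeds[i, ])

  if (k >= 2) {
    ord <- order(-seedD)
    starts <- ord[seq_len(min(n_starts, length(ord)))]
    objective <- function(v) {
      s <- c(v, 1 - sum(v))
      s <- project_bounded_simplex(s, slo, sup, total = 1)
      -dscore(expand(s * rfree))$D
    }
    for (i in starts) {
      s0 <- seeds[i, ] / rfree
      par <- if (k == 2) {
        stats::optimize(objective, lower = slo[1], upper = sup[1],
                        tol = 1e-9)$minimum
      } else {
        stats::optim(s0[-k], objective, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))$par
      }
      s <- project_bounded_simplex(c(par, 1 - sum(par)), slo, sup, total = 1)
      add_point(s * rfree)
    }
  }

  tab <- do.call(rbind, lapply(pool, function(p) {
    compv <- expand(p$sfree)
    row <- as.data.frame(rbind(compv))
    names(row) <- comp
    for (r in names(models)) row[[paste0("pred_", r)]] <- p$preds[[r]]
    for (j in seq_along(goals))
      row[[paste0("d_", goals[[j]]$response)]] <- p$d[j]
    row$D <- p$D
    row
  }))
  tab <- tab[order(-tab$D, do.call(paste, tab[comp])), , drop = FALSE]
  tab <- tab[!duplicated(round(as.matrix(tab[comp]), 6)), , drop = FALSE]
  rownames(tab) <- NULL
  if (max(tab$D) == 0)
    mf_warn(paste0("no composition achieves positive desirability; ",
                   "unmet goal(s): ",
                   paste(vapply(goals, `[[`, "", "response")[
                     pool[[which.max(vapply(pool, `[[`, 0, "D"))]]$d == 0],
                     collapse = ", ")),
            "mixformula_empty_result")
  structure(list(candidates = utils::head(tab, n_top), goals = goals,
                 fixed = fixed, n_starts = n_starts, seed = seed),
            class = "optimization_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.optimization_result <- function(x, ...) {
  cat("Formulation optimization:", nrow(x$candidates),
      "ranked candidates\n")
  print(x$candidates, digits = 4)
  invisible(x)
}

#' Re-rank optimization candidates
#'
#' Stable descending sort of the candidate table by a predicted response or
#' by overall desirability `D`; ties break by `D`, then by lexicographic
#' composition. Selecting the candidate with the highest predicted nMFI, for
#' example, is `rank_candidates(res, "nmfi")`.
#'
#' @param result An `optimization_result`.
#' @param key `"D"` or a response name with a `pred_<name>` column.
#' @return The result with `candidates` reordered.
#' @export
rank_candidates <- function(result, key = "D") {
  tab <- result$candidates
  col <- if (key == "D") "D" else paste0("pred_", key)
  if (!col %in% names(tab))
    mf_stop(paste0("unknown ranking key '", key, "'"),
            "mixformula_goal_error")
  comp <- setdiff(names(tab), grep("^(pred_|d_)|^D$", names(tab), value = TRUE))
  ord <- order(-tab[[col]], -tab$D, do.call(paste, tab[comp]))
  result$candidates <- tab[ord, , drop = FALSE]
  rownames(result$candidates) <- NULL
  result
}
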