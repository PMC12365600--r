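test_that("desirability ramps follow the Derringer-Suich convention", {
  g1 <- goal("y", "maximize", low = 0, target = 1, weight = 1)
  expect_equal(desirability_value(0.5, g1), 0.5)
  expect_equal(desirability_value(c(-1, 0, 1, 5), g1), c(0, 0, 1, 1))
  g2 <- goal("y", "maximize", low = 0, target = 1, weight = 2)
  expect_equal(desirability_value(0.5, g2), 0.25)
  g3 <- goal("y", "minimize", target = 10, high = 20)
  expect_equal(desirability_value(c(5, 15, 25), g3), c(1, 0.5, 0))
  g4 <- goal("y", "target", low = 0, target = 2, high = 6)
  expect_equal(desirability_value(c(1, 2, 4), g4), c(0.5, 1, 0.5))
  g5 <- goal("y", "inrange", low = 1, high = 2)
  expect_equal(desirability_value(c(0.5, 1.5), g5), c(0, 1))
  expect_error(goal("y", "maximize", low = 2, target = 1),
               class = "mixformula_goal_error")
  expect_error(goal("y", "maximize", low = 0, target = 1, importance = 9),
               class = "mixformula_goal_error")
})

test_that("overall desirability is the importance-weighted geometric mean", {
  expect_equal(overall_desirability(c(0.25, 1)), 0.5)
  expect_equal(overall_desirability(c(0.7, 0, 0.9)), 0)
  expect_equal(overall_desirability(c(1, 1, 1)), 1)
  # importance tilts the mean toward the weighted response
  expect_equal(overall_desirability(c(0.25, 1), c(1, 3)), 0.25^(1/4))
  expect_error(overall_desirability(numeric(0)), class = "mixformula_goal_error")
  expect_error(overall_desirability(c(0.5, 1.4)), class = "mixformula_goal_error")
})

test_that("single linear goal optimum lands on the best vertex (grid oracle)", {
  d <- random_simplex_design(9, 3, seed = 500)
  sp <- scheffe_spec(3, "linear")
  y <- drop(scheffe_matrix(d, sp) %*% c(2, 9, 4))   # x2 dominates
  fit <- fit_scheffe(d, y, sp)
  g <- goal("resp", "maximize", low = 0, target = 9, weight = 1)
  b <- unconstrained_bounds(3)
  res <- optimize_formulation(list(resp = fit), list(g), b,
                              n_starts = 10, seed = 501)
  top <- res$candidates[1, ]
  # dense grid oracle over the simplex
  grid <- expand.grid(x1 = seq(0, 1, 0.01), x2 = seq(0, 1, 0.01))
  grid <- grid[grid$x1 + grid$x2 <= 1, ]
  pts <- cbind(grid$x1, grid$x2, 1 - grid$x1 - grid$x2)
  dvals <- desirability_value(predict_response(fit, pts), g)
  expect_gte(top$D, max(dvals) - 1e-3)
  expect_equal(unlist(top[c("x1", "x2", "x3")]), c(x1 = 0, x2 = 1, x3 = 0),
               tolerance = 1e-6)
})

test_that("multistart optimum matches a dense grid on a two-goal problem", {
  d <- random_simplex_design(12, 3, seed = 510)
  sp <- scheffe_spec(3, list(1, 2, 3, c(1, 2)))
  set.seed(511)
  y1 <- drop(scheffe_matrix(d, sp) %*% c(5, 2, 8, 20)) + rnorm(12, 0, 0.1)
  y2 <- drop(scheffe_matrix(d, scheffe_spec(3, "linear")) %*% c(1, 8, 3)) +
    rnorm(12, 0, 0.1)
  f1 <- fit_scheffe(d, y1, sp)
  f2 <- fit_scheffe(d, y2, scheffe_spec(3, "linear"))
  goals <- list(goal("a", "maximize", low = 2, target = 9, weight = 1,
                     importance = 3),
                goal("b", "target", low = 2, target = 5, high = 8,
                     importance = 2))
  b <- unconstrained_bounds(3)
  res <- optimize_formulation(list(a = f1, b = f2), goals, b,
                              n_starts = 20, seed = 512)
  grid <- expand.grid(x1 = seq(0, 1, 0.01), x2 = seq(0, 1, 0.01))
  grid <- grid[grid$x1 + grid$x2 <= 1 + 1e-12, ]
  pts <- cbind(grid$x1, grid$x2, pmax(1 - grid$x1 - grid$x2, 0))
  dA <- desirability_value(predict_response(f1, pts), goals[[1]])
  dB <- desirability_value(predict_response(f2, pts), goals[[2]])
  Dgrid <- mapply(function(a, b) overall_desirability(c(a, b), c(3, 2)),
                  dA, dB)
  expect_gte(res$candidates$D[1], max(Dgrid) - 1e-3)
})

test_that("fixed components are held exactly and candidates stay feasible", {
  d <- builtin_design()
  gt <- builtin_models()
  y <- simulate_responses(d, seed = 520)
  fE <- fit_scheffe(d, y$encapsulation_pct, gt$encapsulation_pct$spec, 1)
  fF <- fit_scheffe(d, y$nmfi, gt$nmfi$spec, -1.5)
  goals <- list(goal("encapsulation_pct", "maximize", low = 40, target = 95,
                     weight = 2, importance = 3),
                goal("nmfi", "maximize", low = 1, target = 3, importance = 5))
  fixed <- c("SM-102" = 0.65, "DMG-PEG2000" = 0.01)
  res <- optimize_formulation(list(encapsulation_pct = fE, nmfi = fF),
                              goals, lnp_bounds(), fixed = fixed,
                              n_starts = 15, seed = 521)
  tab <- res$candidates
  expect_true(all(abs(tab[["SM-102"]] - 0.65) < 1e-12))
  expect_true(all(abs(tab[["DMG-PEG2000"]] - 0.01) < 1e-12))
  comp <- as.matrix(tab[, lnp_bounds()$names])
  expect_equal(unname(rowSums(comp)), rep(1, nrow(comp)), tolerance = 1e-9)
  b <- lnp_bounds()
  expect_true(all(t(comp) >= b$lower - 1e-9 & t(comp) <= b$upper + 1e-9))
  expect_true(all(diff(tab$D) <= 1e-12))
  expect_true(all(tab$D >= 0 & tab$D <= 1))
  expect_error(
    optimize_formulation(list(encapsulation_pct = fE), goals[1], b,
                         fixed = c("SM-102" = 0.99)),
    class = "mixformula_infeasible")
})

test_that("an unsatisfiable goal warns of an empty result", {
  d <- random_simplex_design(9, 3, seed = 530)
  sp <- scheffe_spec(3, "linear")
  y <- drop(scheffe_matrix(d, sp) %*% c(2, 3, 4))
  fit <- fit_scheffe(d, y, sp)
  goals <- list(goal("resp", "maximize", low = 0, target = 3),
                goal("resp", "maximize", low = 100, target = 200))  # hopeless
  expect_warning(
    res <- optimize_formulation(list(resp = fit), goals,
                                unconstrained_bounds(3), n_starts = 4,
                                seed = 531),
    class = "mixformula_empty_result")
  expect_true(all(res$candidates$D == 0))
})

test_that("re-ranking by a response key is stable with D tie-breaks", {
  d <- builtin_design()
  gt <- builtin_models()
  y <- simulate_responses(d, seed = 540)
  fE <- fit_scheffe(d, y$encapsulation_pct, gt$encapsulation_pct$spec, 1)
  fF <- fit_scheffe(d, y$nmfi, gt$nmfi$spec, -1.5)
  goals <- list(goal("encapsulation_pct", "maximize", low = 40, target = 95,
                     importance = 3),
                goal("nmfi", "maximize", low = 1, target = 3, importance = 5))
  res <- optimize_formulation(list(encapsulation_pct = fE, nmfi = fF),
                              goals, lnp_bounds(), n_starts = 10, seed = 541)
  by_nmfi <- rank_candidates(res, "nmfi")
  expect_equal(by_nmfi$candidates$pred_nmfi[1],
               max(res$candidates$pred_nmfi))
  expect_true(all(diff(by_nmfi$candidates$pred_nmfi) <= 1e-12))
  # ranking by D is idempotent on an already-sorted result
  expect_equal(rank_candidates(res, "D")$candidates$D, res$candidates$D)
  expect_error(rank_candidates(res, "nope"), class = "mixformula_goal_error")
})

test_that("raising a response's importance never hurts that response", {
  set.seed(550)
  for (rep in 1:5) {
    d <- random_simplex_design(10, 3, seed = 550 + rep)
    sp <- scheffe_spec(3, "linear")
    beta1 <- runif(3, 0, 10); beta2 <- runif(3, 0, 10)
    f1 <- fit_scheffe(d, drop(scheffe_matrix(d, sp) %*% beta1), sp)
    f2 <- fit_scheffe(d, drop(scheffe_matrix(d, sp) %*% beta2), sp)
    run <- function(imp1) {
      goals <- list(goal("a", "maximize", low = 0, target = max(beta1),
                         importance = imp1),
                    goal("b", "maximize", low = 0, target = max(beta2),
                         importance = 1))
      optimize_formulation(list(a = f1, b = f2), goals,
                           unconstrained_bounds(3), n_starts = 8,
                           seed = 560 + rep)
    }
    lo <- run(1)$candidates$pred_a[1]
    hi <- run(5)$candidates$pred_a[1]
    expect_gte(hi, lo - 1e-6)
  }
})
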