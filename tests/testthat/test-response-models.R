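test_that("nMFI normalization is the ratio to the negative control", {
  expect_equal(normalize_mfi(5000, 5000), 1.0)
  expect_equal(normalize_mfi(2.2 * 1e4, 1e4), 2.2)
  expect_error(normalize_mfi(100, 0), class = "mixformula_domain_error")
})

test_that("power transform and inverse are mutually consistent", {
  expect_identical(power_transform(c(1, 4, 9), 1), c(1, 4, 9))
  expect_equal(power_transform(4, 0.5), 2)
  expect_equal(power_transform(exp(2), 0), 2)
  # frozen hand evaluation of the inverse at a negative exponent
  expect_equal(inverse_power(0.456695, -1.5), 0.456695^(-2/3),
               tolerance = 1e-12)
  expect_equal(signif(inverse_power(0.456695, -1.5), 4), 1.686)
  for (lam in c(-2, -1.5, -0.5, 0, 0.5, 1, 2)) {
    y <- c(0.3, 1, 2.5, 40)
    expect_equal(inverse_power(power_transform(y, lam), lam), y,
                 tolerance = 1e-10)
  }
  # negative lambda is strictly decreasing
  expect_true(all(diff(power_transform(c(1, 2, 3), -1.5)) < 0))
  expect_error(power_transform(c(1, -1), 0.5),
               class = "mixformula_domain_error")
  expect_error(inverse_power(-0.2, -1.5), class = "mixformula_domain_error")
})

test_that("Box-Cox scan recovers generating exponents and is scale invariant", {
  d <- random_simplex_design(15, 3, seed = 41)
  X <- scheffe_matrix(d, scheffe_spec(3, "linear"))
  beta <- c(5, 8, 12)
  set.seed(42)
  y_lin <- drop(X %*% beta) + rnorm(15, 0, 0.5)     # already normal, linear
  sc1 <- boxcox_scan(y_lin, X)
  expect_true(sc1$ci[1] <= 1 && 1 <= sc1$ci[2])
  y_log <- exp(drop(X %*% c(1, 2, 3)) + rnorm(15, 0, 0.3))  # log-normal
  sc0 <- boxcox_scan(y_log, X)
  expect_true(sc0$ci[1] <= 0 && 0 <= sc0$ci[2])
  # rescaling y shifts nothing in the profile shape
  sc_a <- boxcox_scan(y_log, X)
  sc_b <- boxcox_scan(1000 * y_log, X)
  expect_equal(sc_a$grid$loglik - max(sc_a$grid$loglik),
               sc_b$grid$loglik - max(sc_b$grid$loglik), tolerance = 1e-4)
  expect_identical(sc_a$best_lambda, sc_b$best_lambda)
  expect_error(boxcox_scan(c(1, -2, 3), X[1:3, ]),
               class = "mixformula_domain_error")
})

test_that("profile likelihood agrees with the reference Box-Cox implementation", {
  skip_if_not_installed("MASS")
  d <- random_simplex_design(15, 3, seed = 43)
  X <- scheffe_matrix(d, scheffe_spec(3, "linear"))
  set.seed(44)
  y <- exp(drop(X %*% c(1.5, 2, 2.5)) + rnorm(15, 0, 0.4))
  grid <- seq(-2, 2, by = 0.05)
  ours <- boxcox_scan(y, X, grid)
  dat <- data.frame(y = y)
  dat$X <- X
  ref <- do.call(MASS::boxcox,
                 list(y ~ 0 + X, data = dat, lambda = grid, plotit = FALSE))
  expect_equal(ours$best_lambda, ref$x[which.max(ref$y)])
  # the two profiles differ by a constant only
  expect_equal(ours$grid$loglik - max(ours$grid$loglik),
               ref$y - max(ref$y), tolerance = 1e-6)
})

test_that("convenient lambda selection picks round exponents inside the CI", {
  mk <- function(best, lo, hi)
    structure(list(best_lambda = best, ci = c(lo, hi)), class = "boxcox_scan")
  expect_equal(choose_convenient_lambda(mk(0.93, 0.6, 1.3)), 1)
  expect_equal(choose_convenient_lambda(mk(-1.4, -1.9, -0.9)), -1.5)
  expect_equal(choose_convenient_lambda(mk(0.45, 0.3, 0.7)), 0.5)
  expect_warning(out <- choose_convenient_lambda(mk(0.27, 0.22, 0.31)),
                 class = "mixformula_lambda_outside_ci")
  expect_equal(out, 0.5)
})

test_that("Scheffe model matrix expands linear and pair terms", {
  sp <- scheffe_spec(2, list(1, 2, c(1, 2)))
  expect_equal(drop(scheffe_matrix(c(0.5, 0.5), sp)), c(0.5, 0.5, 0.25),
               ignore_attr = TRUE)
  # mixture identity: full linear rows sum to 1
  d <- random_simplex_design(8, 4, seed = 45)
  expect_equal(unname(rowSums(scheffe_matrix(d, scheffe_spec(4, "linear")))),
               rep(1, 8), tolerance = 1e-12)
  ms <- c(0.10, 0.50, 0.385, 0.015)
  expect_equal(drop(scheffe_matrix(ms, scheffe_spec(4, list(c(1, 3))))),
               0.10 * 0.385, ignore_attr = TRUE)
  expect_error(scheffe_spec(4, list(5)), class = "mixformula_spec_error")
})

test_that("least squares recovers noiseless coefficients for all built-in specs", {
  d <- builtin_design()
  y0 <- noiseless_responses(d)
  for (gt in builtin_models()) {
    fit <- fit_scheffe(d, y0[[gt$response]], gt$spec, gt$lambda)
    expect_equal(fit$coefficients, gt$beta, tolerance = 1e-9)
    expect_lt(max(abs(crossprod(scheffe_matrix(fit$design, gt$spec),
                                fit$residuals))), 1e-8)
  }
  # duplicate column -> singular
  expect_error(
    fit_scheffe(d, y0$encapsulation_pct,
                scheffe_spec(4, list(1, 2, 3, 4, c(1, 2), c(1, 2)))),
    class = "mixformula_spec_error")
  tiny <- mixture_design(d$x[1:3, ])
  expect_error(fit_scheffe(tiny, y0$encapsulation_pct[1:3],
                           scheffe_spec(4, "linear")),
               class = "mixformula_underdetermined")
})

test_that("hat diagnostics and fit statistics satisfy their identities", {
  for (seed in 1:4) {
    d <- random_simplex_design(12, 3, seed = seed)
    set.seed(seed + 100)
    y <- drop(scheffe_matrix(d, scheffe_spec(3, "linear")) %*% c(3, 6, 9)) +
      rnorm(12, 0, 0.4)
    sp <- scheffe_spec(3, list(1, 2, 3, c(1, 2)))
    fit <- fit_scheffe(d, y, sp)
    expect_true(all(fit$hat >= -1e-12 & fit$hat <= 1 + 1e-12))
    expect_equal(sum(fit$hat), fit$p, tolerance = 1e-8)
    st <- fit_statistics(fit)
    expect_lte(st$adj_r2, st$r2)
    expect_gte(st$press, fit$SSE)
    expect_lte(st$r2, 1)
    # explicit leave-one-out refits reproduce the PRESS shortcut
    loo <- sum(vapply(seq_len(12), function(i) {
      sub <- mixture_design(d$x[-i, ])
      f_i <- fit_scheffe(sub, y[-i], sp)
      (y[i] - drop(scheffe_matrix(d$x[i, , drop = FALSE], sp) %*%
                     f_i$coefficients))^2
    }, numeric(1)))
    expect_equal(st$press, loo, tolerance = 1e-10)
  }
})

test_that("a perfect fit yields unit R-squared family and zero PRESS", {
  d <- random_simplex_design(9, 3, seed = 46)
  sp <- scheffe_spec(3, "linear")
  y <- drop(scheffe_matrix(d, sp) %*% c(2, 4, 8))
  st <- fit_statistics(fit_scheffe(d, y, sp))
  expect_equal(st$r2, 1, tolerance = 1e-12)
  expect_equal(st$adj_r2, 1, tolerance = 1e-12)
  expect_equal(st$pred_r2, 1, tolerance = 1e-9)
  expect_equal(st$press, 0, tolerance = 1e-18)
  expect_true(is.infinite(st$adeq_precision) || st$adeq_precision > 1e6)
})

test_that("adequacy screening applies the 0.2 gap and precision-4 rules", {
  mk <- function(adj, pred, ap)
    structure(list(adj_r2 = adj, pred_r2 = pred, adeq_precision = ap),
              class = "fit_stats")
  a <- adequacy_check(mk(0.5987, 0.5139, 16.84))
  expect_equal(a$r2_gap, 0.0848, tolerance = 1e-12)
  expect_true(a$r2_gap_ok && a$adeq_precision_ok && a$pass)
  b <- adequacy_check(mk(0.9, 0.6, 10))
  expect_false(b$r2_gap_ok)
  expect_false(b$pass)
  expect_false(adequacy_check(mk(0.9, 0.85, 3.2))$pass)
})

test_that("raw-scale predictions at the hold-out blend match hand evaluation", {
  d <- builtin_design()
  y0 <- noiseless_responses(d)
  gt <- builtin_models()
  ms <- c(0.10, 0.50, 0.385, 0.015)
  # independent hand oracles from the fitted equations at the MS blend
  e_hand <- 57.77 * 0.10 + 62.05 * 0.50 + 106.35 * 0.385 - 177.89 * 0.015
  g_hand <- 25.87 * 0.10 + 9.12 * 0.50 + 4.22 * 0.385 - 77.48 * 0.015 -
    21.14 * 0.05 + 12.29 * 0.5 * 0.385 + 49.40 * 0.5 * 0.015 +
    117.57 * 0.385 * 0.015
  f_hand <- -0.15 * 0.10 + 0.30 * 0.50 + 0.45 * 0.385 + 5.61 * 0.015 +
    1.67 * 0.10 * 0.385
  fitE <- fit_scheffe(d, y0$encapsulation_pct, gt$encapsulation_pct$spec, 1)
  fitG <- fit_scheffe(d, y0$diameter_nm, gt$diameter_nm$spec, 0.5)
  fitF <- fit_scheffe(d, y0$nmfi, gt$nmfi$spec, -1.5)
  expect_equal(predict_response(fitE, ms), e_hand, tolerance = 1e-8)
  expect_equal(predict_response(fitG, ms), g_hand^2, tolerance = 1e-8)
  expect_equal(predict_response(fitF, ms), f_hand^(-2/3), tolerance = 1e-8)
  expect_equal(signif(predict_response(fitE, ms), 3), 75.1)
  expect_equal(signif(predict_response(fitG, ms), 3), 99.4)
  expect_equal(signif(predict_response(fitF, ms), 3), 1.69)
  # negative-lambda domain guard
  neg <- fitF
  neg$coefficients[] <- c(-5, -5, -5, -5, 0)
  expect_error(predict_response(neg, ms),
               class = "mixformula_prediction_domain")
})

test_that("hold-out validation excludes the flagged run and refuses leakage", {
  d <- builtin_design()
  y0 <- noiseless_responses(d)
  gt <- builtin_models()$encapsulation_pct
  fit <- fit_scheffe(d, y0$encapsulation_pct, gt$spec, 1)
  expect_false("MS" %in% fit$run_ids)
  expect_equal(fit$n, 15)
  hold <- mixture_design(d$x["MS", , drop = FALSE], run_ids = "MS")
  tab <- holdout_validation(fit, hold, y0$encapsulation_pct[16])
  expect_equal(nrow(tab), 1)
  expect_equal(tab$rel_error, 0, tolerance = 1e-9)   # noiseless hold-out
  train_leak <- mixture_design(d$x["M03", , drop = FALSE], run_ids = "M03")
  expect_error(holdout_validation(fit, train_leak, 50),
               class = "mixformula_validation_leakage")
  same_comp <- mixture_design(d$x["M03", , drop = FALSE], run_ids = "other")
  expect_error(holdout_validation(fit, same_comp, 50),
               class = "mixformula_validation_leakage")
})

test_that("coefficient confidence intervals cover the generating values", {
  d <- builtin_design()
  gt <- builtin_models()$nmfi
  n_sim <- 300
  cover <- matrix(FALSE, n_sim, 5)
  set.seed(77)
  for (i in seq_len(n_sim)) {
    y <- simulate_responses(d, truth = list(gt))
    fit <- fit_scheffe(d, y$nmfi, gt$spec, gt$lambda)
    X <- scheffe_matrix(fit$design, gt$spec)
    se <- sqrt(fit$MSE * diag(solve(crossprod(X))))
    tq <- qt(0.975, fit$n - fit$p)
    cover[i, ] <- abs(fit$coefficients - gt$beta) <= tq * se
  }
  rate <- mean(cover)
  expect_gte(rate, 0.95 - 3 * sqrt(0.95 * 0.05 / (n_sim * 5)))
  expect_lte(rate, 0.95 + 3 * sqrt(0.95 * 0.05 / (n_sim * 5)))
})
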