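# Power / Box-Cox transforms of formulation responses.

#' Normalized median fluorescence intensity
#'
#' nMFI is the median fluorescence intensity of treated cells divided by
#' that of the negative control, a unitless measure of expression level.
#'
#' @param mfi_treated,mfi_control Fluorescence intensities; `mfi_control`
#'   must be positive. Vectorized.
#' @return `mfi_treated / mfi_control`.
#' @examples
#' normalize_mfi(2.2e4, 1e4)   # 2.2
#' @export
normalize_mfi <- function(mfi_treated, mfi_control) {
  if (any(!is.finite(mfi_control)) || any(mfi_control <= 0))
    mf_stop("control MFI must be positive", "mixformula_domain_error")
  mfi_treated / mfi_control
}

#' Power transform and its inverse
#'
#' Plain power transform \eqn{t = y^\lambda} used on the modeling scale
#' (natural log at \eqn{\lambda = 0}). For \eqn{\lambda < 0} the map is
#' strictly decreasing, so smaller transformed values correspond to larger
#' raw responses. `inverse_power` inverts it: \eqn{y = t^{1/\lambda}}
#' (\eqn{e^t} at 0).
#'
#' @param y Positive response vector (positivity required when `lambda <= 0`
#'   or fractional).
#' @param t Transformed vector (must be positive when `lambda` is negative
#'   or fractional).
#' @param lambda Power exponent, finite scalar.
#' @return Transformed (resp. back-transformed) numeric vector.
#' @examples
#' power_transform(4, 0.5)                 # 2
#' inverse_power(0.456695, -1.5)           # ~1.686, a t^(-2/3) map
#' @export
power_transform <- function(y, lambda) {
  if (!is.finite(lambda)) mf_stop("lambda must be finite",
                                  "mixformula_domain_error")
  if ((lambda <= 0 || lambda %% 1 != 0) && any(y <= 0, na.rm = TRUE))
    mf_stop("response must be strictly positive for this lambda",
            "mixformula_domain_error")
  if (lambda == 0) return(log(y))
  y^lambda
}

#' @rdname power_transform
#' @export
inverse_power <- function(t, lambda) {
  if (!is.finite(lambda)) mf_stop("lambda must be finite",
                                  "mixformula_domain_error")
  if (lambda == 0) return(exp(t))
  if ((lambda < 0 || lambda %% 1 != 0) && any(t <= 0, na.rm = TRUE))
    mf_stop("transformed values must be positive to invert this lambda",
            "mixformula_domain_error")
  t^(1 / lambda)
}

#' Box-Cox profile log-likelihood scan
#'
#' Profiles the Box-Cox exponent over a grid for a given model matrix. Uses
#' the geometric-mean-normalized transform
#' \eqn{z(\lambda) = (y^\lambda - 1)/(\lambda g^{\lambda-1})}
#' (\eqn{z = g \ln y} at \eqn{\lambda = 0}, g the geometric mean of y), whose
#' Jacobian is constant in y, so profile log-likelihoods are comparable
#' across \eqn{\lambda}: \eqn{\ell(\lambda) = -(n/2)\ln(SSE_\lambda/n)} after
#' regressing \eqn{z(\lambda)} on `X`. The ~95% confidence interval collects
#' grid values with \eqn{\ell} within \eqn{\chi^2_{1,0.95}/2} of the maximum.
#' The curve is invariant to rescaling y by a positive constant.
#'
#' @param y Strictly positive response vector.
#' @param X Model matrix (e.g. from [scheffe_matrix]).
#' @param lambda_grid Grid of exponents; the default covers \[-3, 3\].
#' @return Object of class `boxcox_scan`: `grid` data frame
#'   (`lambda`, `loglik`), `best_lambda`, `ci` (length-2 vector).
#' @seealso [choose_convenient_lambda]
#' @export
boxcox_scan <- function(y, X, lambda_grid = seq(-3, 3, by = 0.05)) {
  if (any(!is.finite(y)) || any(y <= 0))
    mf_stop("Box-Cox scan requires strictly positive responses",
            "mixformula_domain_error")
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) mf_stop("X and y sizes differ", "mixformula_domain_error")
  g <- exp(mean(log(y)))
  ll <- vapply(lambda_grid, function(lam) {
    z <- if (lam == 0) g * log(y) else (y^lam - 1) / (lam * g^(lam - 1))
    sse <- sum(stats::lm.fit(X, z)$residuals^2)
    -(n / 2) * log(sse / n)
  }, numeric(1))
  best <- lambda_grid[which.max(ll)]
  cut <- max(ll) - stats::qchisq(0.95, 1) / 2
  inside <- lambda_grid[ll >= cut]
  structure(list(grid = data.frame(lambda = lambda_grid, loglik = ll),
                 best_lambda = best, ci = range(inside)),
            class = "boxcox_scan")
}

#' @export
print.boxcox_scan <- function(x, ...) {
  cat(sprintf("Box-Cox scan: best lambda = %.3g, ~95%% CI [%.3g, %.3g]\n",
              x$best_lambda, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Round a Box-Cox estimate to a convenient exponent
#'
#' Practitioners report round exponents (1, 0.5, -1.5, ...) rather than the
#' raw likelihood maximizer. Returns the convenient value inside the scan's
#' confidence interval closest to the maximizer; if none lies inside, the
#' nearest convenient value overall with a warning.
#'
#' @param scan A [boxcox_scan] result.
#' @param convenient Candidate exponents
#'   (default `-2, -1.5, -1, -0.5, 0, 0.5, 1, 2`).
#' @return A single numeric lambda.
#' @export
choose_convenient_lambda <- function(scan,
                                     convenient = c(-2, -1.5, -1, -0.5,
                                                    0, 0.5, 1, 2)) {
  inside <- convenient[convenient >= scan$ci[1] & convenient <= scan$ci[2]]
  if (length(inside) == 0) {
    mf_warn("no convenient lambda inside the confidence interval; using nearest",
            "mixformula_lambda_outside_ci")
    inside <- convenient
  }
  inside[which.min(abs(inside - scan$best_lambda))]
}
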