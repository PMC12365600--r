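#' Component bounds for a constrained mixture region
#'
#' Defines the feasible region of a mixture experiment: each component
#' proportion is restricted to `[lower, upper]` and all proportions sum to 1.
#' The region is the intersection of the unit simplex with these box
#' constraints (a bounded "extreme-vertices" region).
#'
#' @param names Character vector of component identifiers (length >= 2).
#' @param lower,upper Numeric vectors of per-component proportion limits,
#'   same length as `names`, each pair satisfying `0 <= lower < upper <= 1`.
#'
#' @return An object of class `component_bounds` with fields `names`,
#'   `lower` and `upper` (named numeric vectors).
#'
#' @details The region is non-empty iff `sum(lower) <= 1 <= sum(upper)`;
#'   violating bounds raise a classed error (`mixformula_region_empty`).
#'
#' @examples
#' component_bounds(c("x1", "x2", "x3"), lower = c(0, 0, 0), upper = c(1, 1, 1))
#' lnp_bounds()
#' @export
component_bounds <- function(names, lower, upper) {
  if (!is.character(names) || length(names) < 2 || anyDuplicated(names) > 0)
    mf_stop("'names' must be >= 2 unique component identifiers",
            "mixformula_bounds_error")
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(names) || length(upper) != length(names))
    mf_stop("'lower' and 'upper' must match 'names' in length",
            "mixformula_bounds_error")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    mf_stop("bounds must be finite", "mixformula_bounds_error")
  if (any(lower < 0) || any(upper > 1) || any(lower >= upper))
    mf_stop("each component needs 0 <= lower < upper <= 1",
            "mixformula_bounds_error")
  if (sum(lower) > 1 + 1e-12 || sum(upper) < 1 - 1e-12)
    mf_stop(sprintf(
      "bounds define an empty mixture region (sum(lower) = %.4f, sum(upper) = %.4f)",
      sum(lower), sum(upper)), "mixformula_region_empty")
  structure(
    list(names = names,
         lower = stats::setNames(lower, names),
         upper = stats::setNames(upper, names)),
    class = "component_bounds")
}

#' Reference lipid bounds of the four-component LNP design space
#'
#' Molar-fraction ranges of the four lipids in the Spikevax-type LNP design
#' space: DSPC 5--40%, SM-102 15--65%, cholesterol 15--65%,
#' DMG-PEG2000 1--10%.
#'
#' @return A [component_bounds] object for components
#'   `DSPC`, `SM-102`, `cholesterol`, `DMG-PEG2000`.
#' @export
lnp_bounds <- function() {
  component_bounds(
    c("DSPC", "SM-102", "cholesterol", "DMG-PEG2000"),
    lower = c(0.05, 0.15, 0.15, 0.01),
    upper = c(0.40, 0.65, 0.65, 0.10))
}

#' @export
print.component_bounds <- function(x, ...) {
  cat("Mixture component bounds (", length(x$names), " components)\n", sep = "")
  print(data.frame(component = x$names, lower = x$lower, upper = x$upper,
                   row.names = NULL))
  invisible(x)
}

# TRUE for rows of `x` inside the bounded simplex region (up to tol)
in_bounds <- function(x, bounds, tol = 1e-9) {
  x <- rbind(x)
  ok_lo <- sweep(x, 2, bounds$lower, ">=") | abs(sweep(x, 2, bounds$lower, "-")) <= tol
  ok_up <- sweep(x, 2, bounds$upper, "<=") | abs(sweep(x, 2, bounds$upper, "-")) <= tol
  rowSums(!ok_lo) == 0 & rowSums(!ok_up) == 0
}
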