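# Derringer-Suich desirability functions for multi-response formulation
# goals.

#' Define a desirability goal for one response
#'
#' Derringer-Suich goal: maps a raw-scale response to a desirability in
#' \[0, 1\]. `maximize` ramps from 0 at `low` to 1 at `target` (exponent
#' `weight`); `minimize` mirrors it from `target` down to 0 at `high`;
#' `target` is a two-sided ramp peaking at `target`; `inrange` is the
#' indicator of `[low, high]`.
#'
#' @param response Name of the fitted response this goal applies to.
#' @param direction One of `"maximize"`, `"minimize"`, `"target"`,
#'   `"inrange"`.
#' @param low,target,high Raw-scale breakpoints; requirements per direction:
#'   maximize `low < target`, minimize `target < high`, target
#'   `low < target < high`, inrange `low < high`.
#' @param weight Ramp exponent `w > 0`; `w > 1` demands values close to the
#'   target before granting desirability.
#' @param importance Integer 1--5; relative exponent in the overall
#'   geometric mean.
#' @return An object of class `desirability_goal`.
#' @examples
#' goal("encapsulation_pct", "maximize", low = 40, target = 95, weight = 2)
#' @export
goal <- function(response, direction = c("maximize", "minimize", "target",
                                         "inrange"),
                 low = NULL, target = NULL, high = NULL,
                 weight = 1, importance = 3) {
  direction <- match.arg(direction)
  if (!is.numeric(weight) || weight <= 0)
    mf_stop("weight must be > 0", "mixformula_goal_error")
  if (importance != round(importance) || importance < 1 || importance > 5)
    mf_stop("importance must be an integer in 1..5", "mixformula_goal_error")
  ok <- switch(direction,
    maximize = !is.null(low) && !is.null(target) && low < target,
    minimize = !is.null(target) && !is.null(high) && target < high,
    target   = !is.null(low) && !is.null(target) && !is.null(high) &&
               low < target && target < high,
    inrange  = !is.null(low) && !is.null(high) && low < high)
  if (!ok) mf_stop(sprintf("invalid bounds for a '%s' goal", direction),
                   "mixformula_goal_error")
  structure(list(response = response, direction = direction,
                 low = low, target = target, high = high,
                 weight = weight, importance = as.integer(importance)),
            class = "desirability_goal")
}

#' @export
print.desirability_goal <- function(x, ...) {
  cat(sprintf("Goal: %s %s (L=%s T=%s U=%s, weight %g, importance %d)\n",
              x$direction, x$response,
              format(x$low), format(x$target), format(x$high),
              x$weight, x$importance))
  invisible(x)
}

#' Per-goal desirability of a response value
#'
#' @param y Raw-scale response value(s).
#' @param goal A [goal()] object.
#' @return Desirability in \[0, 1\], vectorized over `y`.
#' @examples
#' g <- goal("y", "maximize", low = 0, target = 1, weight = 2)
#' desirability_value(0.5, g)   # 0.25
#' @export
desirability_value <- function(y, goal) {
  w <- goal$weight
  d <- switch(goal$direction,
    maximize = pmin(pmax((y - goal$low) / (goal$target - goal$low), 0), 1)^w,
    minimize = pmin(pmax((goal$high - y) / (goal$high - goal$target), 0), 1)^w,
    target = ifelse(
      y <= goal$target,
      pmin(pmax((y - goal$low) / (goal$target - goal$low), 0), 1)^w,
      pmin(pmax((goal$high - y) / (goal$high - goal$target), 0), 1)^w),
    inrange = as.numeric(y >= goal$low & y <= goal$high))
  d
}

#' Overall desirability (importance-weighted geometric mean)
#'
#' \eqn{D = (\prod_i d_i^{r_i})^{1/\sum_i r_i}}; any fully unmet goal
#' (d = 0) forces D = 0.
#'
#' @param d Vector of per-goal desirabilities in \[0, 1\].
#' @param importance Integer importances aligned with `d` (default all 1).
#' @return Scalar D in \[0, 1\].
#' @examples
#' overall_desirability(c(0.25, 1))   # 0.5
#' @export
overall_desirability <- function(d, importance = rep(1L, length(d))) {
  if (length(d) == 0) mf_stop("no goals supplied", "mixformula_goal_error")
  if (any(d < -1e-12) || any(d > 1 + 1e-12))
    mf_stop("desirabilities must lie in [0, 1]", "mixformula_goal_error")
  if (length(importance) != length(d))
    mf_stop("importance length mismatch", "mixformula_goal_error")
  if (any(d == 0)) return(0)
  exp(sum(importance * log(d)) / sum(importance))
}
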