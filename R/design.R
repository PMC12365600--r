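#' Construct a mixture design
#'
#' A mixture design is an n x q matrix of component proportions (each row
#' summing to 1) with run labels and a per-run validation flag. Input may be
#' in percent (rows summing to ~100, the convention of formulation tables) or
#' in proportions (rows summing to ~1); percent input is divided by 100.
#'
#' @param x Numeric matrix (or data frame) of compositions, one run per row.
#' @param run_ids Character run labels; defaults to rownames of `x` or
#'   `R01`, `R02`, ...
#' @param is_validation Logical vector flagging hold-out runs excluded from
#'   model fitting; default all `FALSE`.
#' @param bounds Optional [component_bounds] attached to the design (used by
#'   [validate_design] and bound-aware operations).
#' @param tol Relative tolerance for classifying row sums as percent or
#'   proportion scale (default 1%). Rows outside both gates are an error.
#'
#' @return An object of class `mixture_design`: list with `x` (proportion
#'   matrix, rows exactly renormalized to sum 1), `run_ids`, `is_validation`,
#'   `bounds`.
#' @examples
#' mixture_design(rbind(c(60, 30, 10), c(20, 20, 60)))
#' @export
mixture_design <- function(x, run_ids = NULL, is_validation = NULL,
                           bounds = NULL, tol = 0.01) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) mf_stop("compositions must be finite numbers",
                                  "mixformula_design_error")
  if (any(x < 0)) mf_stop("compositions must be non-negative",
                          "mixformula_design_error")
  if (is.null(run_ids)) {
    run_ids <- rownames(x)
    if (is.null(run_ids)) run_ids <- sprintf("R%02d", seq_len(nrow(x)))
  }
  if (anyDuplicated(run_ids) > 0)
    mf_stop("duplicate run_ids", "mixformula_design_error")
  if (is.null(is_validation)) is_validation <- rep(FALSE, nrow(x))
  is_validation <- as.logical(is_validation)
  s <- rowSums(x)
  pct <- abs(s - 100) / 100 <= tol
  prop <- abs(s - 1) <= tol
  if (all(pct) && !all(prop)) {
    x <- x / 100
  } else if (!all(prop)) {
    bad <- run_ids[!(pct | prop)]
    if (length(bad) == 0) bad <- run_ids[!prop]  # mixed percent/proportion file
    mf_stop(paste0("malformed composition rows (sum far from 1 and 100): ",
                   paste(bad, collapse = ", ")),
            "mixformula_malformed_row")
  }
  x <- renormalize_rows(x)
  rownames(x) <- run_ids
  if (!is.null(bounds)) {
    if (is.null(colnames(x))) colnames(x) <- bounds$names
    if (!identical(colnames(x), bounds$names))
      mf_stop("design columns do not match bounds components",
              "mixformula_design_error")
  }
  structure(list(x = x, run_ids = run_ids, is_validation = is_validation,
                 bounds = bounds),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("Mixture design: ", nrow(x$x), " runs x ", ncol(x$x), " components",
      if (any(x$is_validation))
        sprintf(" (%d validation)", sum(x$is_validation)) else "",
      "\n", sep = "")
  df <- as.data.frame(round(100 * x$x, 4))
  df$is_validation <- x$is_validation
  print(utils::head(df, 20))
  if (nrow(df) > 20) cat("... (", nrow(df) - 20, " more rows)\n", sep = "")
  invisible(x)
}

# coerce a design / matrix / vector to a proportion matrix
design_matrix <- function(design) {
  if (inherits(design, "mixture_design")) return(design$x)
  if (is.null(dim(design)))
    design <- matrix(design, nrow = 1,
                     dimnames = list(NULL, names(design)))
  as.matrix(design)
}

#' Validate a mixture design against bounds
#'
#' Reports, per run, violations of the mixture constraint (row sum different
#' from 1) and of component bounds. A reporting operation: it never errors.
#'
#' @param design A [mixture_design] (or plain proportion matrix).
#' @param bounds A [component_bounds]; defaults to the bounds attached to the
#'   design, if any.
#' @param tol Absolute tolerance on row sums and bound comparisons.
#' @return A data frame with columns `run_id`, `type` (`row_sum` or `bounds`),
#'   and `detail`; zero rows when the design is valid.
#' @examples
#' validate_design(builtin_design())          # empty report
#' @export
validate_design <- function(design, bounds = NULL, tol = 1e-9) {
  x <- design_matrix(design)
  ids <- if (inherits(design, "mixture_design")) design$run_ids
         else sprintf("R%02d", seq_len(nrow(x)))
  if (is.null(bounds) && inherits(design, "mixture_design"))
    bounds <- design$bounds
  out <- list()
  s <- rowSums(x)
  bad_sum <- abs(s - 1) > tol
  for (i in which(bad_sum))
    out[[length(out) + 1]] <- data.frame(
      run_id = ids[i], type = "row_sum",
      detail = sprintf("row sums to %.6f", s[i]))
  if (!is.null(bounds)) {
    for (i in seq_len(nrow(x))) {
      lo <- x[i, ] < bounds$lower - tol
      up <- x[i, ] > bounds$upper + tol
      if (any(lo | up))
        out[[length(out) + 1]] <- data.frame(
          run_id = ids[i], type = "bounds",
          detail = paste(bounds$names[lo | up], collapse = ", "))
    }
  }
  if (length(out) == 0)
    return(data.frame(run_id = character(), type = character(),
                      detail = character()))
  do.call(rbind, out)
}

#' Build a ratio series of mixtures with fixed components
#'
#' Holds a set of components at fixed proportions and splits the remainder
#' between a pair of components at prescribed ratios, one run per ratio. This
#' is the construction behind a DSPC-to-cholesterol ratio series at fixed
#' ionizable-lipid and PEG-lipid levels: with SM-102 at 0.65 and DMG-PEG2000
#' at 0.01, the remainder 0.34 is split so DSPC/cholesterol equals each ratio.
#'
#' @param fixed Named numeric vector of fixed component proportions
#'   (`0 < sum(fixed) < 1`).
#' @param pair Character vector of the two components receiving the
#'   remainder, in (numerator, denominator) order.
#' @param ratios Positive numerator/denominator ratios, one run each.
#' @param run_ids Optional labels; default `N1`, `N2`, ...
#' @param bounds Optional [component_bounds] attached to the result.
#' @return A [mixture_design] with components `c(pair, names(fixed))`
#'   reordered to the bounds' component order when bounds are given.
#' @examples
#' ratio_series(c("SM-102" = 0.65, "DMG-PEG2000" = 0.01),
#'              pair = c("DSPC", "cholesterol"),
#'              ratios = c(5.8, 2.4, 1.27, 0.36, 0.13))
#' @export
ratio_series <- function(fixed, pair, ratios, run_ids = NULL, bounds = NULL) {
  if (is.null(names(fixed)) || length(pair) != 2)
    mf_stop("'fixed' must be named and 'pair' of length 2",
            "mixformula_design_error")
  if (sum(fixed) >= 1)
    mf_stop("fixed components consume the whole mixture (sum >= 1)",
            "mixformula_infeasible")
  if (sum(fixed) <= 0)
    mf_stop("sum of fixed components must be positive", "mixformula_infeasible")
  ratios <- as.numeric(ratios)
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    mf_stop("ratios must be positive", "mixformula_domain_error")
  r <- 1 - sum(fixed)
  first <- r * ratios / (1 + ratios)
  second <- r / (1 + ratios)
  x <- cbind(first, second,
             matrix(rep(fixed, each = length(ratios)), nrow = length(ratios)))
  colnames(x) <- c(pair, names(fixed))
  if (!is.null(bounds)) x <- x[, bounds$names, drop = FALSE]
  if (is.null(run_ids)) run_ids <- paste0("N", seq_along(ratios))
  mixture_design(x, run_ids = run_ids, bounds = bounds)
}
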