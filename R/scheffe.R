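#' Scheffe canonical polynomial model specification
#'
#' A Scheffe canonical polynomial in mixture proportions has no intercept:
#' it is built from linear blending terms \eqn{x_i} and binary (nonlinear)
#' blending terms \eqn{x_i x_j}. Because \eqn{\sum_i x_i = 1}, the full set
#' of linear terms spans the constant, so the model is intercept-free by
#' construction.
#'
#' @param q Number of mixture components.
#' @param terms Either a list of integer vectors (each of length 1 or 2,
#'   indices in `1..q`) or one of the shorthands `"linear"` (all `q`
#'   singletons) and `"quadratic"` (all singletons plus all pairs).
#' @param names Optional component names used to label terms.
#' @return An object of class `scheffe_spec`: list with `terms` (list of
#'   sorted integer vectors), `q`, `labels`.
#' @examples
#' scheffe_spec(3, "quadratic")
#' scheffe_spec(4, list(1, 2, 3, 4, c(1, 3)))   # linear blending + x1*x3
#' @export
scheffe_spec <- function(q, terms = "linear", names = NULL) {
  q <- as.integer(q)
  if (q < 2) mf_stop("need q >= 2 components", "mixformula_spec_error")
  if (is.character(terms)) {
    terms <- match.arg(terms, c("linear", "quadratic"))
    base <- as.list(seq_len(q))
    if (terms == "quadratic") {
      prs <- utils::combn(q, 2, simplify = FALSE)
      terms <- c(base, prs)
    } else terms <- base
  }
  terms <- lapply(terms, function(t) sort(as.integer(t)))
  if (length(terms) < 1) mf_stop("at least one term required",
                                 "mixformula_spec_error")
  for (t in terms) {
    if (!length(t) %in% c(1L, 2L) || any(t < 1L) || any(t > q) ||
        anyDuplicated(t) > 0)
      mf_stop("terms must be singletons or pairs of distinct indices in 1..q",
              "mixformula_spec_error")
  }
  keys <- vapply(terms, paste, "", collapse = ":")
  if (anyDuplicated(keys) > 0)
    mf_stop("duplicate terms in specification", "mixformula_spec_error")
  if (is.null(names)) names <- paste0("x", seq_len(q))
  labels <- vapply(terms, function(t) paste(names[t], collapse = ":"), "")
  structure(list(terms = terms, q = q, labels = labels),
            class = "scheffe_spec")
}

#' @export
print.scheffe_spec <- function(x, ...) {
  cat("Scheffe model: q =", x$q, "components,", length(x$terms), "terms\n")
  cat(" ", paste(x$labels, collapse = " + "), "\n")
  invisible(x)
}

n_terms <- function(spec) length(spec$terms)

#' Scheffe model matrix
#'
#' Expands compositions into the model matrix of a Scheffe canonical
#' polynomial: column j is the product of the proportions named by term j.
#' There is no intercept column; for a full linear specification every row
#' sums to 1 (the mixture identity).
#'
#' @param design A [mixture_design], matrix of proportions, or a single
#'   composition vector.
#' @param spec A [scheffe_spec].
#' @return An n x p numeric matrix with columns labelled by term.
#' @examples
#' scheffe_matrix(rbind(c(0.5, 0.5)), scheffe_spec(2, list(1, 2, c(1, 2))))
#' @export
scheffe_matrix <- function(design, spec) {
  x <- design_matrix(design)
  if (ncol(x) != spec$q)
    mf_stop("design has wrong number of components for this spec",
            "mixformula_spec_error")
  X <- vapply(spec$terms,
              function(t) apply(x[, t, drop = FALSE], 1, prod),
              numeric(nrow(x)))
  X <- matrix(X, nrow = nrow(x))
  colnames(X) <- spec$labels
  rownames(X) <- rownames(x)
  X
}
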