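# internal helpers shared across the package

# classed error so callers can distinguish failure modes with tryCatch()
mf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mixformula_error")))
}

mf_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "mixformula_warning")))
}

# row-normalize a composition matrix; rows must already be close to sum 1
renormalize_rows <- function(x) {
  sweep(x, 1, rowSums(x), "/")
}

fmt_comp <- function(x) {
  paste(sprintf("%.4f", x), collapse = ", ")
}
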