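# CSV I/O for designs and response tables, small formulation utilities,
# and plain-text reporting.

#' Read and write mixture designs as CSV
#'
#' Schema: `run_id,<component names...>[,is_validation]`. Composition values
#' may be percentages (rows summing to ~100, the formulation-table
#' convention) or proportions (rows summing to ~1); the file must be
#' consistent — rows deviating more than 1% from both scales, or a mix of
#' scales, raise a malformed-row error naming the runs. Write emits percent
#' values rounded to 6 decimals, so a write/read round-trip is the identity
#' at that precision.
#'
#' @param path CSV file path.
#' @param bounds Optional [component_bounds] attached on read.
#' @param design A [mixture_design] to write.
#' @return `read_design` returns a [mixture_design]; `write_design` returns
#'   `path` invisibly.
#' @export
read_design <- function(path, bounds = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "run_id")
    mf_stop("design file must start with a 'run_id' column",
            "mixformula_io_error")
  hasval <- "is_validation" %in% names(df)
  compcols <- setdiff(names(df), c("run_id", "is_validation"))
  x <- as.matrix(df[compcols])
  if (!is.numeric(x)) mf_stop("non-numeric composition values",
                              "mixformula_io_error")
  s <- rowSums(x)
  pct <- abs(s - 100) / 100 <= 0.01
  prop <- abs(s - 1) <= 0.01
  if (!(all(pct) || all(prop))) {
    bad <- df$run_id[!(pct | prop)]
    if (length(bad) == 0) bad <- df$run_id[!(if (sum(pct) >= sum(prop)) pct else prop)]
    mf_stop(paste0("malformed composition rows in ", path, ": ",
                   paste(bad, collapse = ", ")),
            "mixformula_malformed_row")
  }
  mixture_design(x, run_ids = as.character(df$run_id),
                 is_validation = if (hasval) as.logical(df$is_validation),
                 bounds = bounds)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  df <- data.frame(run_id = design$run_ids,
                   round(100 * design$x, 6),
                   is_validation = design$is_validation,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write response tables as CSV
#'
#' Schema: `run_id,encapsulation_pct,diameter_nm,nmfi` (any subset of the
#' response columns; missing values allowed as empty cells / NA). Run ids
#' must all belong to the supplied design; non-positive diameters or nMFI
#' values, or encapsulation outside (0, 100], are domain errors naming the
#' offending cell.
#'
#' @param path CSV file path.
#' @param design The [mixture_design] the responses belong to.
#' @param responses A response data frame (as from [simulate_responses]) to
#'   write.
#' @return `read_responses` returns a data frame aligned to the file's row
#'   order; `write_responses` returns `path` invisibly.
#' @export
read_responses <- function(path, design) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"run_id" %in% names(df))
    mf_stop("response file needs a 'run_id' column", "mixformula_io_error")
  unknown <- setdiff(df$run_id, design$run_ids)
  if (length(unknown) > 0)
    mf_stop(paste0("response run_id(s) not in design: ",
                   paste(unknown, collapse = ", ")),
            "mixformula_join_error")
  check_pos <- function(col, lo_ok = FALSE, hi = Inf) {
    if (!col %in% names(df)) return()
    v <- df[[col]]
    bad <- which(!is.na(v) & (v <= 0 | v > hi))
    if (length(bad) > 0)
      mf_stop(sprintf("out-of-domain %s for run %s (value %g)",
                      col, df$run_id[bad[1]], v[bad[1]]),
              "mixformula_domain_error")
  }
  check_pos("encapsulation_pct", hi = 100)
  check_pos("diameter_nm")
  check_pos("nmfi")
  df
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Final concentration after a volumetric dilution
#'
#' Mixing `parts_stock` volumes of a stock at `stock_pct` (% w/v) with
#' `parts_diluent` volumes of suspension gives
#' `stock_pct * parts_stock / (parts_stock + parts_diluent)`. A 1:1 dilution
#' of a 40% sucrose stock yields 20% final.
#'
#' @param stock_pct Stock concentration (% w/v, >= 0).
#' @param parts_stock,parts_diluent Volume parts (non-negative, positive
#'   total).
#' @return Final concentration (% w/v).
#' @examples
#' dilution_concentration(40, 1, 1)   # 20
#' @export
dilution_concentration <- function(stock_pct, parts_stock = 1,
                                   parts_diluent = 1) {
  if (any(c(stock_pct, parts_stock, parts_diluent) < 0))
    mf_stop("negative inputs", "mixformula_domain_error")
  if (parts_stock + parts_diluent <= 0)
    mf_stop("total volume parts must be positive", "mixformula_domain_error")
  stock_pct * parts_stock / (parts_stock + parts_diluent)
}

#' Size of a full factorial design
#'
#' Product of the number of levels per factor; four factors at four levels
#' each give 256 runs — the combinatorial burden an optimal mixture design
#' avoids.
#'
#' @param levels_per_factor Integer vector of level counts (each >= 1).
#' @return Integer-valued count.
#' @examples
#' full_factorial_size(c(4, 4, 4, 4))   # 256
#' @export
full_factorial_size <- function(levels_per_factor) {
  if (any(levels_per_factor < 1) ||
      any(levels_per_factor != round(levels_per_factor)))
    mf_stop("level counts must be integers >= 1", "mixformula_domain_error")
  prod(levels_per_factor)
}

format_equation <- function(name, fit) {
  co <- fit$coefficients
  parts <- sprintf("%s %.2f %s", ifelse(co < 0, "-", "+"), abs(co), names(co))
  parts[1] <- sub("^\\+ ", "", parts[1])
  sprintf("%s^%s = %s", name, format(fit$lambda), paste(parts, collapse = " "))
}

#' Write a plain-text modeling report
#'
#' Emits deterministic text files into `dir`: `equations.txt` (fitted
#' equations with coefficients to 2 decimals on their transformed scales),
#' `statistics.tsv` (std_dev, mean, cv_pct, r2, adj_r2, pred_r2,
#' adeq_precision per model), `adequacy.tsv` (screening flags), and
#' optionally `selection_trace.csv` and `candidates.csv`. Identical inputs
#' yield byte-identical files.
#'
#' @param fits Named list of [scheffe_fit] objects.
#' @param stats Named list of [fit_statistics] results aligned with `fits`.
#' @param traces Optional named list of `selection_trace` objects.
#' @param opt_result Optional `optimization_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
report_formulation <- function(fits, stats, traces = NULL, opt_result = NULL,
                               dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  eqf <- file.path(dir, "equations.txt")
  writeLines(vapply(names(fits),
                    function(nm) format_equation(nm, fits[[nm]]), ""),
             eqf)
  written <- c(written, eqf)

  stf <- file.path(dir, "statistics.tsv")
  sdf <- do.call(rbind, lapply(names(stats), function(nm) {
    s <- stats[[nm]]
    data.frame(model = nm,
               std_dev = sprintf("%.6g", s$std_dev),
               mean = sprintf("%.6g", s$mean),
               cv_pct = sprintf("%.6g", s$cv_pct),
               r2 = sprintf("%.4f", s$r2),
               adj_r2 = sprintf("%.4f", s$adj_r2),
               pred_r2 = sprintf("%.4f", s$pred_r2),
               adeq_precision = sprintf("%.6g", s$adeq_precision))
  }))
  utils::write.table(sdf, stf, sep = "\t", row.names = FALSE, quote = FALSE)
  written <- c(written, stf)

  adf <- file.path(dir, "adequacy.tsv")
  ad <- do.call(rbind, lapply(names(stats), function(nm) {
    a <- adequacy_check(stats[[nm]])
    data.frame(model = nm, r2_gap = sprintf("%.4f", a$r2_gap),
               r2_gap_ok = a$r2_gap_ok,
               adeq_precision_ok = a$adeq_precision_ok, pass = a$pass)
  }))
  utils::write.table(ad, adf, sep = "\t", row.names = FALSE, quote = FALSE)
  written <- c(written, adf)

  if (!is.null(traces)) {
    trf <- file.path(dir, "selection_trace.csv")
    tr <- do.call(rbind, lapply(names(traces), function(nm) {
      cbind(model = nm, traces[[nm]]$steps)
    }))
    utils::write.csv(format(tr, digits = 8), trf, row.names = FALSE,
                     quote = FALSE)
    written <- c(written, trf)
  }
  if (!is.null(opt_result)) {
    cf <- file.path(dir, "candidates.csv")
    utils::write.csv(format(opt_result$candidates, digits = 8), cf,
                     row.names = FALSE, quote = FALSE)
    written <- c(written, cf)
  }
  invisible(written)
}
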