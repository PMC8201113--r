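#' Read / write per-attribute results tables
#'
#' Results are written as comma-delimited UTF-8 text mirroring the layout of
#' the classical Kano report table: the six category counts (A, Q, I, R, M,
#' O), the modal classification, and CS/DS rounded to 2 decimals, followed by
#' the exact coefficient values so that a write/read cycle is lossless.
#'
#' @param results A non-empty results tibble from [kano_analyze()] or
#'   [analyze_counts()].
#' @param path File path.
#' @return `read_results()` returns the results tibble; `write_results()`
#'   returns `path` invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("results must be a non-empty results table", call. = FALSE)
  }
  need <- c("attr_id", count_cols(), "n_valid", "classification",
            "cs", "ds", "cs_exact", "ds_exact")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols)) {
    stop("results table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- results[, need]
  # fixed 2-dp formatting for the report columns; *_exact keep full precision
  out$cs <- ifelse(is.na(out$cs), NA, sprintf("%.2f", out$cs))
  out$ds <- ifelse(is.na(out$ds), NA, sprintf("%.2f", out$ds))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    attr_id = readr::col_integer(),
    n_A = readr::col_integer(), n_Q = readr::col_integer(),
    n_I = readr::col_integer(), n_R = readr::col_integer(),
    n_M = readr::col_integer(), n_O = readr::col_integer(),
    n_valid = readr::col_integer(),
    classification = readr::col_character(),
    cs = readr::col_double(), ds = readr::col_double(),
    cs_exact = readr::col_double(), ds_exact = readr::col_double()),
    progress = FALSE)
  tibble::as_tibble(df)
}
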