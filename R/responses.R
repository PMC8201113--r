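answer_cols <- function(instrument) {
  as.vector(rbind(paste0("a", instrument$attr_id, "_f"),
                  paste0("a", instrument$attr_id, "_d")))
}

#' Validate a respondent-level response table
#'
#' A response table is wide: one row per respondent with `respondent_id`,
#' `age_group`, `gender`, `hospital`, then an `a<k>_f` / `a<k>_d` column pair
#' per attribute holding Likert codes 1..5. A blank cell is a missing answer;
#' an answer pair counts as valid only when BOTH codes are present and in
#' range, so per-attribute valid n may differ across attributes.
#'
#' @param data A data frame in the wide layout above.
#' @param instrument A [kano_instrument()]; defaults to [default_instrument()].
#' @return The validated table as a `kano_responses` tibble (the instrument is
#'   attached as an attribute).
#' @export
kano_responses <- function(data, instrument = default_instrument()) {
  stopifnot(is.data.frame(data))
  demo <- c("respondent_id", "age_group", "gender", "hospital")
  need <- c(demo, answer_cols(instrument))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("response table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data[, need])
  out$respondent_id <- as.character(out$respondent_id)
  if (anyDuplicated(out$respondent_id)) {
    stop("duplicate respondent_id: ",
         paste(unique(out$respondent_id[duplicated(out$respondent_id)]), collapse = ", "),
         call. = FALSE)
  }
  check_vocab <- function(col, vocab) {
    bad <- !is.na(out[[col]]) & !(out[[col]] %in% vocab)
    if (any(bad)) {
      stop("invalid ", col, " value(s): ",
           paste(unique(out[[col]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  check_vocab("age_group", age_groups())
  check_vocab("gender", genders())
  check_vocab("hospital", hospitals())
  for (col in answer_cols(instrument)) {
    v <- suppressWarnings(as.integer(out[[col]]))
    raw_present <- !is.na(out[[col]]) & out[[col]] != ""
    bad <- which(raw_present & (is.na(v) | v < 1L | v > 5L))
    if (length(bad)) {
      stop("answer code outside 1..5 in column '", col, "', row ", bad[1],
           " (value: ", out[[col]][bad[1]], ")", call. = FALSE)
    }
    out[[col]] <- v
  }
  attr(out, "instrument") <- instrument
  class(out) <- c("kano_responses", class(out))
  out
}

responses_instrument <- function(responses, instrument = NULL) {
  if (!is.null(instrument)) return(instrument)
  instr <- attr(responses, "instrument")
  if (is.null(instr)) default_instrument() else instr
}

#' Read / write respondent-level response tables
#'
#' Comma-delimited UTF-8 text with a mandatory header row, in the wide layout
#' documented in [kano_responses()]. Blank cells are read as missing answers.
#'
#' @param path File path.
#' @param instrument A [kano_instrument()] the table must conform to.
#' @return `read_responses()` returns a `kano_responses` tibble.
#' @export
read_responses <- function(path, instrument = default_instrument()) {
  data <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  kano_responses(data, instrument)
}

#' @param responses A `kano_responses` table.
#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(tibble::as_tibble(unclass_responses(responses)), path, na = "")
  invisible(path)
}

unclass_responses <- function(responses) {
  class(responses) <- setdiff(class(responses), "kano_responses")
  attr(responses, "instrument") <- NULL
  responses
}

#' Long table of valid answer pairs
#'
#' Pivots a wide response table to one row per (respondent, attribute) pair,
#' keeping only pairs where both the functional and the dysfunctional code
#' are present.
#'
#' @inheritParams read_responses
#' @param responses A `kano_responses` table.
#' @return A tibble with columns `respondent_id`, `attr_id`, `functional`,
#'   `dysfunctional`.
#' @export
valid_pairs <- function(responses, instrument = NULL) {
  instrument <- responses_instrument(responses, instrument)
  ids <- instrument$attr_id
  pieces <- lapply(ids, function(k) {
    f <- responses[[paste0("a", k, "_f")]]
    d <- responses[[paste0("a", k, "_d")]]
    ok <- !is.na(f) & !is.na(d)
    tibble::tibble(respondent_id = responses$respondent_id[ok],
                   attr_id = k, functional = f[ok], dysfunctional = d[ok])
  })
  dplyr::bind_rows(pieces)
}
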