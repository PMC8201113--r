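#' Round half away from zero
#'
#' Report rounding used for the CS/DS columns: exact halves round away from
#' zero (0.575 -> 0.58, -0.825 -> -0.83), unlike base [round()]'s
#' round-half-even. A 1e-9 guard absorbs binary floating-point representation
#' error; it cannot flip any ratio of integers with denominator <= 1e6.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# count columns in the classical report-table order
count_cols <- function() paste0("n_", c("A", "Q", "I", "R", "M", "O"))

validate_counts <- function(counts) {
  stopifnot(is.data.frame(counts))
  need <- c("attr_id", count_cols())
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    stop("counts table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in count_cols()) {
    v <- counts[[col]]
    if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
      stop("category counts must be non-negative integers (column ", col, ")",
           call. = FALSE)
    }
  }
  tibble::as_tibble(counts)
}

#' Aggregate a response table to per-attribute category counts
#'
#' Classifies every valid answer pair via the evaluation matrix and tallies
#' the six categories per attribute. Pairs with either side missing are
#' excluded, so the per-attribute total equals that attribute's number of
#' valid pairs. The result does not depend on respondent order.
#'
#' @param responses A [kano_responses()] table.
#' @param instrument A [kano_instrument()]; defaults to the one attached to
#'   `responses`.
#' @param matrix Evaluation matrix, default [kano_matrix()].
#' @return A tibble with one row per instrument attribute: `attr_id`,
#'   `n_A`, `n_O`, `n_M`, `n_I`, `n_R`, `n_Q`, and `n_valid` (their sum).
#' @export
aggregate_counts <- function(responses, instrument = NULL, matrix = kano_matrix()) {
  instrument <- responses_instrument(responses, instrument)
  pairs <- valid_pairs(responses, instrument)
  base <- tibble::tibble(attr_id = instrument$attr_id)
  for (col in count_cols()) base[[col]] <- 0L
  if (nrow(pairs) > 0) {
    pairs$category <- classify_pair(pairs$functional, pairs$dysfunctional, matrix)
    tab <- table(factor(pairs$attr_id, levels = instrument$attr_id),
                 factor(pairs$category, levels = kano_categories()))
    for (cat in kano_categories()) {
      base[[paste0("n_", cat)]] <- as.integer(tab[, cat])
    }
  }
  base$n_valid <- as.integer(rowSums(base[, count_cols()]))
  base
}

#' Modal Kano classification of an attribute
#'
#' Assigns each attribute the category with the maximal count; ties are
#' broken by the priority list `tie_order` (earliest wins).
#'
#' @param counts A counts table as returned by [aggregate_counts()] (columns
#'   `n_A` ... `n_Q`), one row per attribute.
#' @param tie_order Category priority, default [kano_tie_order()].
#' @return Character vector of category codes, one per row of `counts`.
#' @export
#' @examples
#' classify_attribute(data.frame(attr_id = 1, n_A = 2, n_Q = 0, n_I = 3,
#'                               n_R = 0, n_M = 127, n_O = 118))
classify_attribute <- function(counts, tie_order = kano_tie_order()) {
  counts <- validate_counts(counts)
  if (!setequal(tie_order, kano_categories())) {
    stop("tie_order must be a permutation of the six Kano categories", call. = FALSE)
  }
  m <- as.matrix(counts[, paste0("n_", tie_order)])
  apply(m, 1, function(r) {
    if (sum(r) == 0) stop("cannot classify an attribute with all-zero counts",
                          call. = FALSE)
    tie_order[which.max(r)]  # which.max takes the first maximum => tie_order wins
  })
}

coefficient_denominator <- function(counts) {
  counts$n_A + counts$n_O + counts$n_M + counts$n_I
}

#' Berger satisfaction and dissatisfaction coefficients
#'
#' `satisfaction_coefficient()` computes CS = (A + O) / (A + O + M + I): the
#' average gain in satisfaction when the attribute is provided, in \[0, 1\].
#' `dissatisfaction_coefficient()` computes DS = -(M + O) / (A + O + M + I):
#' the average loss when it is not, in \[-1, 0\] (reported with a negative
#' sign). Reverse and questionable responses are excluded from the
#' denominator. When A + O + M + I = 0 (all responses reverse/questionable)
#' the coefficient is undefined and `NA` is returned.
#'
#' @param counts A counts table (columns `n_A` ... `n_Q`), one row per
#'   attribute.
#' @return Numeric vector, one exact (unrounded) value per row; `NA` where
#'   undefined.
#' @export
#' @examples
#' cnt <- data.frame(attr_id = 1, n_A = 24, n_Q = 0, n_I = 21,
#'                   n_R = 0, n_M = 85, n_O = 120)
#' satisfaction_coefficient(cnt)     # 144/250 = 0.576
#' dissatisfaction_coefficient(cnt)  # -205/250 = -0.82
satisfaction_coefficient <- function(counts) {
  counts <- validate_counts(counts)
  den <- coefficient_denominator(counts)
  ifelse(den > 0, (counts$n_A + counts$n_O) / den, NA_real_)
}

#' @rdname satisfaction_coefficient
#' @export
dissatisfaction_coefficient <- function(counts) {
  counts <- validate_counts(counts)
  den <- coefficient_denominator(counts)
  ifelse(den > 0, -(counts$n_M + counts$n_O) / den, NA_real_)
}

#' Per-attribute Kano results from a counts table
#'
#' Adds the modal classification and the CS/DS coefficients (exact and
#' rounded to 2 decimals, half away from zero) to a per-attribute counts
#' table. This is the entry point when only aggregated category counts are
#' available, e.g. counts transcribed from a published report.
#'
#' @inheritParams classify_attribute
#' @param digits Decimal places for the rounded report columns.
#' @return A tibble: the count columns plus `n_valid`, `classification`,
#'   `cs`, `ds` (rounded) and `cs_exact`, `ds_exact`.
#' @export
analyze_counts <- function(counts, tie_order = kano_tie_order(), digits = 2) {
  counts <- validate_counts(counts)
  out <- counts[, c("attr_id", count_cols())]
  out$n_valid <- as.integer(rowSums(out[, count_cols()]))
  out$classification <- NA_character_
  pos <- out$n_valid > 0
  if (any(pos)) {
    out$classification[pos] <- classify_attribute(out[pos, ], tie_order)
  }
  out$cs_exact <- satisfaction_coefficient(out)
  out$ds_exact <- dissatisfaction_coefficient(out)
  out$cs <- round_half_up(out$cs_exact, digits)
  out$ds <- round_half_up(out$ds_exact, digits)
  out[, c("attr_id", count_cols(), "n_valid", "classification",
          "cs", "ds", "cs_exact", "ds_exact")]
}

#' Full Kano analysis of a respondent-level table
#'
#' Composition of [aggregate_counts()] and [analyze_counts()]: classify every
#' valid answer pair, tally per attribute, assign the modal category and
#' compute the CS/DS coefficients.
#'
#' @inheritParams aggregate_counts
#' @inheritParams analyze_counts
#' @return A per-attribute results tibble; see [analyze_counts()].
#' @export
#' @examples
#' res <- kano_analyze(hospital_survey_responses())
#' summarize_classifications(res)
kano_analyze <- function(responses, instrument = NULL, matrix = kano_matrix(),
                         tie_order = kano_tie_order(), digits = 2) {
  instrument <- responses_instrument(responses, instrument)
  counts <- aggregate_counts(responses, instrument, matrix)
  analyze_counts(counts, tie_order = tie_order, digits = digits)
}

#' Tally attribute classifications
#'
#' Counts how many attributes fall in each Kano category; the values sum to
#' the number of attributes analysed.
#'
#' @param results A results tibble from [kano_analyze()] or [analyze_counts()].
#' @return A tibble with columns `classification` (all six categories, in
#'   [kano_categories()] order) and `n`.
#' @export
summarize_classifications <- function(results) {
  lv <- kano_categories()
  tab <- table(factor(results$classification, levels = lv))
  tibble::tibble(classification = lv, n = as.integer(tab))
}
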