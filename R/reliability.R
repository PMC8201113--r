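#' Item matrix for reliability analysis
#'
#' Extracts the numeric respondent x item matrix the reliability analysis
#' runs on. `item_set` selects the functional items, the dysfunctional
#' items, or all paired items (the default: both items of every attribute).
#' Rows with any missing value among the selected items are dropped
#' (listwise deletion).
#'
#' @param responses A [kano_responses()] table.
#' @param instrument A [kano_instrument()]; defaults to the one attached to
#'   `responses`.
#' @param item_set One of `"all_paired"`, `"functional"`, `"dysfunctional"`.
#' @return A numeric matrix (respondents x items) with item column names.
#' @export
item_matrix <- function(responses, instrument = NULL,
                        item_set = c("all_paired", "functional", "dysfunctional")) {
  item_set <- match.arg(item_set)
  instrument <- responses_instrument(responses, instrument)
  cols <- switch(item_set,
    all_paired    = answer_cols(instrument),
    functional    = paste0("a", instrument$attr_id, "_f"),
    dysfunctional = paste0("a", instrument$attr_id, "_d"))
  m <- as.matrix(as.data.frame(responses)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Standardized Cronbach's alpha
#'
#' Internal-consistency coefficient based on the mean pairwise Pearson
#' correlation r-bar among k items:
#' alpha = k * r-bar / (1 + (k - 1) * r-bar).
#' Because it is computed from correlations, it is invariant under linear
#' rescaling of any item, and tends to 1 as r-bar tends to 1.
#'
#' @param m A numeric respondent x item matrix with no missing values
#'   (see [item_matrix()]); at least 2 rows and 2 columns, every item with
#'   nonzero variance.
#' @return The alpha value (a number <= 1).
#' @export
#' @examples
#' m <- cbind(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
#' standardized_alpha(m)  # perfectly correlated items -> 1
standardized_alpha <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 items for alpha", call. = FALSE)
  if (nrow(m) < 2) stop("need at least 2 respondents for alpha", call. = FALSE)
  if (anyNA(m)) stop("item matrix contains missing values; apply listwise deletion first",
                     call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance item(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  k <- ncol(m)
  r <- stats::cor(m)
  rbar <- mean(r[lower.tri(r)])
  k * rbar / (1 + (k - 1) * rbar)
}

#' Reliability threshold check
#'
#' Flags whether an alpha value reaches the conventional acceptability
#' threshold (0.7 by default; the boundary itself counts as acceptable).
#'
#' @param alpha A reliability coefficient.
#' @param threshold Acceptability cut-off, default 0.7.
#' @return Logical: `alpha >= threshold`.
#' @export
alpha_acceptable <- function(alpha, threshold = 0.7) {
  if (is.na(alpha)) stop("alpha is undefined", call. = FALSE)
  alpha >= threshold
}
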