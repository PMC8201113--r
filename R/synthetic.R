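#' Representative answer cells per Kano category
#'
#' One designated (functional, dysfunctional) code pair per category, each
#' mapping back to its category under the canonical evaluation matrix:
#' A -> (1,3), O -> (1,5), M -> (3,5), I -> (3,3), R -> (5,1), Q -> (1,1).
#' Used to realise category-level probability specifications as answer pairs
#' and to expand aggregated counts into respondent-level tables exactly.
#'
#' @return A named list of length-2 integer vectors `c(functional, dysfunctional)`.
#' @export
representative_cells <- function() {
  list(A = c(1L, 3L), O = c(1L, 5L), M = c(3L, 5L),
       I = c(3L, 3L), R = c(5L, 1L), Q = c(1L, 1L))
}

default_demographic_probs <- function() {
  # marginal strata of the reference two-hospital survey (n = 250):
  # ages 67/101/60/22, gender 122 male / 128 female, hospitals 128/122
  list(
    age_group = c(`18-34` = 67, `35-54` = 101, `55-74` = 60, `75+` = 22) / 250,
    gender    = c(male = 122, female = 128) / 250,
    hospital  = c(barton = 128, kaelin = 122) / 250
  )
}

check_probs <- function(p, what) {
  if (anyNA(p) || any(p < 0)) stop(what, " probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) stop(what, " probabilities must sum to 1", call. = FALSE)
  p
}

category_to_cell_probs <- function(category_probs) {
  check_probs(category_probs, "category")
  missing_cats <- setdiff(names(category_probs), kano_categories())
  if (length(missing_cats)) {
    stop("unknown categories in category_probs: ",
         paste(missing_cats, collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, 5, 5, dimnames = list(functional = 1:5, dysfunctional = 1:5))
  cells <- representative_cells()
  for (cat in names(category_probs)) {
    cell <- cells[[cat]]
    m[cell[1], cell[2]] <- m[cell[1], cell[2]] + category_probs[[cat]]
  }
  m
}

#' Specify a synthetic survey profile
#'
#' A profile drives [simulate_responses()]: per attribute, a probability
#' distribution over the 25 (functional, dysfunctional) answer cells, plus
#' marginal demographic distributions and a seed. The cell distribution can
#' be given directly (`cell_probs`, a 5 x 5 matrix) or at category level
#' (`category_probs`, a named vector over the six Kano categories realised
#' via [representative_cells()]). Either may also be a list keyed by
#' attribute id (as character) to vary across attributes; unkeyed values
#' apply to every attribute.
#'
#' @param n_respondents Number of respondents to simulate (default 250, the
#'   reference survey's sample size).
#' @param category_probs Named numeric vector over categories, or a list of
#'   such vectors keyed by attribute id.
#' @param cell_probs A 5 x 5 probability matrix (rows functional, columns
#'   dysfunctional), or a list of such matrices keyed by attribute id.
#'   Overrides `category_probs` for the attributes it names.
#' @param demographics Named list of marginal probability vectors for
#'   `age_group`, `gender`, `hospital`; defaults to the reference survey's
#'   strata.
#' @param seed Integer seed recorded in the profile; simulation is
#'   reproducible given the profile.
#' @return A `kano_profile` object.
#' @export
#' @examples
#' p <- kano_profile(n_respondents = 50, category_probs = c(O = 0.7, I = 0.3),
#'                   seed = 1)
kano_profile <- function(n_respondents = 250,
                         category_probs = c(O = 0.5, M = 0.2, A = 0.1,
                                            I = 0.15, R = 0.03, Q = 0.02),
                         cell_probs = NULL,
                         demographics = default_demographic_probs(),
                         seed = NULL) {
  if (!is.numeric(n_respondents) || n_respondents < 1) {
    stop("n_respondents must be >= 1", call. = FALSE)
  }
  for (field in c("age_group", "gender", "hospital")) {
    check_probs(demographics[[field]], field)
  }
  check_cat <- function(p) {
    if (is.numeric(p)) category_to_cell_probs(p) else invisible(NULL)
  }
  if (is.list(category_probs)) lapply(category_probs, check_cat) else check_cat(category_probs)
  structure(list(n_respondents = as.integer(n_respondents),
                 category_probs = category_probs,
                 cell_probs = cell_probs,
                 demographics = demographics,
                 seed = seed),
            class = "kano_profile")
}

profile_cell_matrix <- function(profile, attr_id) {
  key <- as.character(attr_id)
  pick <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
      if (!is.null(x[[key]])) x[[key]] else x[[".default"]]
    } else x
  }
  cp <- pick(profile$cell_probs)
  if (!is.null(cp)) {
    if (!is.matrix(cp) || !identical(dim(cp), c(5L, 5L))) {
      stop("cell_probs must be a 5 x 5 matrix", call. = FALSE)
    }
    return(matrix(check_probs(as.vector(cp), "cell"), 5, 5))
  }
  catp <- pick(profile$category_probs)
  if (is.null(catp)) stop("no probability specification for attribute ", attr_id,
                          call. = FALSE)
  category_to_cell_probs(catp)
}

sample_levels <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Simulate a respondent-level survey
#'
#' Draws `n_respondents` records: each attribute's answer pair independently
#' from that attribute's cell distribution, demographics independently from
#' their marginal distributions. Reproducible: the same profile (including
#' its seed) yields the identical table. The seed is recorded in the output's
#' `"seed"` attribute.
#'
#' @param profile A [kano_profile()].
#' @param instrument A [kano_instrument()], default [default_instrument()].
#' @param seed Overrides `profile$seed` if given.
#' @return A `kano_responses` tibble.
#' @export
simulate_responses <- function(profile, instrument = default_instrument(),
                               seed = profile$seed) {
  stopifnot(inherits(profile, "kano_profile"))
  if (is.null(seed)) seed <- 0L
  n <- profile$n_respondents
  out <- withr::with_seed(as.integer(seed), {
    tbl <- tibble::tibble(
      respondent_id = sprintf("s%04d", seq_len(n)),
      age_group = sample_levels(n, profile$demographics$age_group),
      gender    = sample_levels(n, profile$demographics$gender),
      hospital  = sample_levels(n, profile$demographics$hospital))
    for (k in instrument$attr_id) {
      m <- profile_cell_matrix(profile, k)
      # flatten row-major so index = (functional - 1) * 5 + dysfunctional
      idx <- sample.int(25L, n, replace = TRUE, prob = as.vector(t(m)))
      tbl[[paste0("a", k, "_f")]] <- (idx - 1L) %/% 5L + 1L
      tbl[[paste0("a", k, "_d")]] <- (idx - 1L) %% 5L + 1L
    }
    tbl
  })
  res <- kano_responses(out, instrument)
  attr(res, "seed") <- as.integer(seed)
  res
}

largest_remainder <- function(n, probs) {
  exact <- n * probs
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

quota_demographics <- function(n, probs = default_demographic_probs()) {
  assign_quota <- function(p) rep(names(p), times = largest_remainder(n, p))
  tibble::tibble(age_group = assign_quota(probs$age_group),
                 gender    = assign_quota(probs$gender),
                 hospital  = assign_quota(probs$hospital))
}

#' Expand aggregated category counts to a respondent-level table
#'
#' Deterministic inverse of [aggregate_counts()]: every counted response is
#' realised as its category's representative answer cell, so re-aggregating
#' the expansion returns the input counts exactly. Attributes are expanded
#' in the fixed category order A, Q, I, R, M, O and aligned by respondent
#' index; if attributes have unequal totals, the shorter ones are padded
#' with missing pairs. Demographics are assigned by deterministic quota from
#' the reference survey's marginal strata.
#'
#' @param counts A per-attribute counts table (columns `attr_id`,
#'   `n_A` ... `n_Q`).
#' @param instrument A [kano_instrument()] covering all `attr_id`s in
#'   `counts`; default [default_instrument()].
#' @return A `kano_responses` tibble with `max(row totals)` respondents
#'   (zero rows if all counts are zero).
#' @export
#' @examples
#' cnt <- data.frame(attr_id = 1, n_A = 2, n_Q = 0, n_I = 1,
#'                   n_R = 0, n_M = 3, n_O = 4)
#' tab <- expand_counts(cnt, kano_instrument(
#'   data.frame(attr_id = 1, dimension = "efficiency", text = "x")))
#' aggregate_counts(tab)[, c("n_A", "n_M", "n_O")]
expand_counts <- function(counts, instrument = default_instrument()) {
  counts <- validate_counts(counts)
  extra <- setdiff(counts$attr_id, instrument$attr_id)
  if (length(extra)) {
    stop("counts contain attr_id(s) not in the instrument: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  totals <- rowSums(counts[, count_cols()])
  n <- if (nrow(counts)) max(totals) else 0
  tbl <- tibble::tibble(respondent_id = sprintf("r%04d", seq_len(n)))
  tbl <- dplyr::bind_cols(tbl, quota_demographics(n))
  cells <- representative_cells()
  fill_order <- c("A", "Q", "I", "R", "M", "O")  # printed column order
  for (k in instrument$attr_id) {
    f <- rep(NA_integer_, n)
    d <- rep(NA_integer_, n)
    row <- counts[counts$attr_id == k, ]
    if (nrow(row) == 1) {
      cats <- rep(fill_order, times = as.integer(unlist(row[, paste0("n_", fill_order)])))
      if (length(cats)) {
        f[seq_along(cats)] <- vapply(cells[cats], `[`, integer(1), 1L)
        d[seq_along(cats)] <- vapply(cells[cats], `[`, integer(1), 2L)
      }
    }
    tbl[[paste0("a", k, "_f")]] <- f
    tbl[[paste0("a", k, "_d")]] <- d
  }
  kano_responses(tbl, instrument)
}

#' Bundled reference survey data
#'
#' `hospital_survey_counts()` returns the published per-attribute category
#' counts of the reference 250-user survey of two hospital outpatient
#' services (31 attributes, each row summing to 250).
#' `hospital_survey_responses()` expands those counts deterministically into
#' a 250-respondent table (see [expand_counts()]) whose demographics match
#' the survey's marginal strata exactly, so the full respondent-level
#' pipeline can be exercised without the unavailable raw data.
#'
#' @return A counts tibble, or a `kano_responses` tibble with 250 rows.
#' @export
#' @examples
#' counts <- hospital_survey_counts()
#' all(rowSums(counts[, -1]) == 250)
hospital_survey_counts <- function() {
  path <- system.file("extdata", "hospital_survey_counts.csv", package = "kanoqual")
  df <- utils::read.csv(path)
  validate_counts(df)
}

#' @rdname hospital_survey_counts
#' @export
hospital_survey_responses <- function() {
  expand_counts(hospital_survey_counts(), default_instrument())
}
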