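#' The six Kano quality categories
#'
#' A = attractive, O = one-dimensional, M = must-be, I = indifferent,
#' R = reverse, Q = questionable (a contradictory answer pair).
#'
#' @return Character vector of the six category codes.
#' @export
kano_categories <- function() c("A", "O", "M", "I", "R", "Q")

#' Default tie-break priority for attribute classification
#'
#' When two or more categories tie for the maximal count, the earliest
#' category in this priority list wins. The default is the conservative
#' must-be-first convention: M > O > A > I > R > Q.
#'
#' @return Character vector: a permutation of [kano_categories()].
#' @export
kano_tie_order <- function() c("M", "O", "A", "I", "R", "Q")

#' The Kano evaluation matrix
#'
#' The 5 x 5 lookup that maps a (functional, dysfunctional) answer-code pair
#' to a Kano category. The default is the canonical table: row = functional
#' code, column = dysfunctional code;
#' (1,1) = Q, (1,2..4) = A, (1,5) = O, (2..4,1) = R,
#' the middle 3 x 3 block = I, (2..4,5) = M, (5,1..4) = R, (5,5) = Q.
#' The matrix is a replaceable input to every classification function, not a
#' hard-coded constant.
#'
#' @return A 5 x 5 character matrix with dimnames `functional` 1..5 and
#'   `dysfunctional` 1..5, each cell one of [kano_categories()].
#' @export
#' @examples
#' kano_matrix()["1", "5"]  # presence liked, absence disliked -> "O"
kano_matrix <- function() {
  m <- matrix(c(
    "Q", "A", "A", "A", "O",
    "R", "I", "I", "I", "M",
    "R", "I", "I", "I", "M",
    "R", "I", "I", "I", "M",
    "R", "R", "R", "R", "Q"),
    nrow = 5, byrow = TRUE,
    dimnames = list(functional = 1:5, dysfunctional = 1:5))
  validate_kano_matrix(m)
}

validate_kano_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(5L, 5L))) {
    stop("evaluation matrix must be 5 x 5", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(m)), kano_categories())
  if (length(bad)) {
    stop("evaluation matrix contains unknown categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m
}

#' Read an evaluation matrix from CSV
#'
#' Expects a header `functional,d1,d2,d3,d4,d5` and five rows giving the
#' category for each (functional, dysfunctional) cell. The bundled default is
#' at `system.file("extdata", "evaluation_matrix.csv", package = "kanoqual")`.
#'
#' @param path File path.
#' @return A 5 x 5 character matrix as in [kano_matrix()].
#' @export
read_kano_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("functional", paste0("d", 1:5))) || nrow(df) != 5) {
    stop("evaluation matrix file must have header functional,d1..d5 and 5 rows",
         call. = FALSE)
  }
  m <- as.matrix(df[order(df$functional), paste0("d", 1:5)])
  dimnames(m) <- list(functional = 1:5, dysfunctional = 1:5)
  validate_kano_matrix(m)
}

#' Classify one or more answer pairs
#'
#' Looks each (functional, dysfunctional) code pair up in the evaluation
#' matrix. Vectorised over the two code arguments.
#'
#' @param functional,dysfunctional Integer Likert codes in 1..5.
#' @param matrix A 5 x 5 evaluation matrix, default [kano_matrix()].
#' @return Character vector of Kano category codes.
#' @export
#' @examples
#' classify_pair(1, 5)  # "O": satisfaction when present, dissatisfaction when absent
#' classify_pair(3, 3)  # "I": indifferent either way
#' classify_pair(5, 1)  # "R": reverse preference
#' classify_pair(1, 1)  # "Q": contradictory answers
classify_pair <- function(functional, dysfunctional, matrix = kano_matrix()) {
  validate_kano_matrix(matrix)
  f <- as.integer(functional)
  d <- as.integer(dysfunctional)
  if (length(f) != length(d)) stop("code vectors must have equal length", call. = FALSE)
  ok <- !is.na(f) & !is.na(d)
  if (any(f[ok] < 1L | f[ok] > 5L | d[ok] < 1L | d[ok] > 5L)) {
    stop("answer codes must be in 1..5", call. = FALSE)
  }
  out <- rep(NA_character_, length(f))
  out[ok] <- matrix[cbind(f[ok], d[ok])]
  out
}
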