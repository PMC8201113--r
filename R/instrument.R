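#' Five-point Likert answer scale of the paired Kano items
#'
#' Both the functional item ("how do you feel if the attribute is present?")
#' and the dysfunctional item ("... if it is absent?") of every attribute are
#' answered on the same five-point scale.
#'
#' @return A named character vector of length 5; names are the codes "1".."5".
#' @export
#' @examples
#' likert_scale()
likert_scale <- function() {
  c(`1` = "I like it",
    `2` = "I hope it is so",
    `3` = "I am neutral",
    `4` = "I can accept it being that way",
    `5` = "I dislike it that way")
}

#' Closed vocabularies for demographics and dimensions
#'
#' @return A character vector of admissible values.
#' @export
#' @rdname vocabularies
age_groups <- function() c("18-34", "35-54", "55-74", "75+")

#' @export
#' @rdname vocabularies
genders <- function() c("male", "female")

#' @export
#' @rdname vocabularies
hospitals <- function() c("barton", "kaelin")

#' @export
#' @rdname vocabularies
instrument_dimensions <- function() {
  c("health_personnel", "non_health_personnel",
    "facilities_equipment_tangibles", "efficiency")
}

#' Construct a Kano instrument
#'
#' An instrument is the questionnaire's structure: an ordered set of service
#' attributes, each belonging to one dimension and carrying an implicit pair
#' of items (functional and dysfunctional, both on the [likert_scale()]).
#'
#' @param attributes A data frame with columns `attr_id` (unique integers),
#'   `dimension` (one of [instrument_dimensions()]), and `text`.
#' @param name Optional instrument name.
#' @return A `kano_instrument`: a tibble with one row per attribute.
#' @export
kano_instrument <- function(attributes, name = "Kano instrument") {
  stopifnot(is.data.frame(attributes))
  need <- c("attr_id", "dimension", "text")
  missing_cols <- setdiff(need, names(attributes))
  if (length(missing_cols)) {
    stop("instrument is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(attributes[, need])
  out$attr_id <- as.integer(out$attr_id)
  if (anyNA(out$attr_id)) stop("attr_id must be integer", call. = FALSE)
  if (anyDuplicated(out$attr_id)) {
    dup <- out$attr_id[duplicated(out$attr_id)]
    stop("duplicate attr_id in instrument: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(out$dimension), instrument_dimensions())
  if (length(bad)) {
    stop("unknown dimension name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(out, "name") <- name
  attr(out, "demographic_fields") <- c("age_group", "gender", "hospital")
  class(out) <- c("kano_instrument", class(out))
  out
}

#' The bundled 31-attribute hospital quality instrument
#'
#' The default instrument used throughout the package: 31 service attributes
#' in four dimensions (10 health-personnel, 4 non-health-personnel,
#' 6 facilities/equipment/tangibles, 11 efficiency), derived from the
#' HEALTHQUAL scale for outpatient hospital services. With one functional and
#' one dysfunctional item per attribute plus three demographic questions the
#' full questionnaire has 65 questions.
#'
#' @return A `kano_instrument` with 31 rows.
#' @export
#' @examples
#' instr <- default_instrument()
#' table(instr$dimension)
default_instrument <- function() {
  path <- system.file("extdata", "healthqual_instrument.yaml", package = "kanoqual")
  read_instrument(path)
}

#' Read / write an instrument definition
#'
#' Instruments are stored as a small YAML document: a `dimensions` list, each
#' entry holding a `name` and its `attributes` (each with `id` and `text`).
#'
#' @param path File path.
#' @return `read_instrument()` returns a `kano_instrument`.
#' @export
read_instrument <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$dimensions)) {
    stop("instrument file has no 'dimensions' section: ", path, call. = FALSE)
  }
  rows <- lapply(doc$dimensions, function(dim) {
    if (is.null(dim$name)) stop("dimension without a name in ", path, call. = FALSE)
    do.call(rbind, lapply(dim$attributes, function(a) {
      data.frame(attr_id = a$id, dimension = dim$name, text = a$text,
                 stringsAsFactors = FALSE)
    }))
  })
  kano_instrument(do.call(rbind, rows),
                  name = if (is.null(doc$name)) basename(path) else doc$name)
}

#' @param instrument A `kano_instrument`.
#' @rdname read_instrument
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "kano_instrument"))
  dims <- unique(instrument$dimension)
  doc <- list(
    name = attr(instrument, "name"),
    demographic_fields = attr(instrument, "demographic_fields"),
    dimensions = lapply(dims, function(d) {
      sub <- instrument[instrument$dimension == d, ]
      list(name = d,
           attributes = lapply(seq_len(nrow(sub)), function(i) {
             list(id = sub$attr_id[i], text = sub$text[i])
           }))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.kano_instrument <- function(x, ...) {
  cat("<kano_instrument> ", attr(x, "name"), "\n", sep = "")
  cat(nrow(x), " attributes in ", length(unique(x$dimension)), " dimensions; ",
      2L * nrow(x), " paired items + ",
      length(attr(x, "demographic_fields")), " demographic fields\n", sep = "")
  NextMethod()
  invisible(x)
}
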