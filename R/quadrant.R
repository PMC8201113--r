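#' Quadrant-chart coordinates for attribute results
#'
#' Maps each attribute to the point (x = |DS|, y = CS) in the unit square.
#' Attributes with undefined coefficients are dropped with a warning.
#'
#' @param results A results tibble from [kano_analyze()] or [analyze_counts()].
#' @param instrument A [kano_instrument()] supplying labels and dimensions;
#'   default [default_instrument()].
#' @return A tibble with `attr_id`, `label`, `dimension`, `x`, `y`,
#'   `classification`.
#' @export
quadrant_points <- function(results, instrument = default_instrument()) {
  undef <- is.na(results$cs_exact) | is.na(results$ds_exact)
  if (any(undef)) {
    warning("skipping attribute(s) with undefined coefficients: ",
            paste(results$attr_id[undef], collapse = ", "), call. = FALSE)
  }
  res <- results[!undef, ]
  meta <- instrument[match(res$attr_id, instrument$attr_id), c("attr_id", "text", "dimension")]
  tibble::tibble(attr_id = res$attr_id,
                 label = meta$text,
                 dimension = meta$dimension,
                 x = abs(res$ds_exact),
                 y = res$cs_exact,
                 classification = res$classification)
}

#' Which quadrant a (|DS|, CS) point falls in
#'
#' Convention: attractive = low |DS|, high CS; one-dimensional = high |DS|,
#' high CS; must-be = high |DS|, low CS; indifferent = low |DS|, low CS.
#' Points on a boundary fall to the low side.
#'
#' @param x `|DS|` values in \[0, 1\].
#' @param y CS values in \[0, 1\].
#' @param split Quadrant boundary on both axes, default 0.5.
#' @return Character vector of quadrant names.
#' @export
#' @examples
#' quadrant_of(0.82, 0.576)  # "one_dimensional"
#' quadrant_of(0, 0)         # "indifferent"
quadrant_of <- function(x, y, split = 0.5) {
  ifelse(x > split,
         ifelse(y > split, "one_dimensional", "must_be"),
         ifelse(y > split, "attractive", "indifferent"))
}

#' CS-|DS| quadrant chart
#'
#' The classical Berger chart: one point per attribute at (|DS|, CS), with
#' quadrant lines at `split` on both axes and the four quadrants labelled.
#' Facetted by instrument dimension by default.
#'
#' @inheritParams quadrant_points
#' @param split Quadrant boundary, default 0.5.
#' @param facet Facet the chart by dimension (default) or plot all
#'   attributes on one panel.
#' @return A ggplot object; printing or [ggplot2::ggsave()] renders it.
#' @export
#' @examples
#' res <- analyze_counts(hospital_survey_counts())
#' p <- plot_quadrants(res)
plot_quadrants <- function(results, instrument = default_instrument(),
                           split = 0.5, facet = TRUE) {
  pts <- quadrant_points(results, instrument)
  corners <- tibble::tibble(
    x = c(split / 2, (1 + split) / 2, (1 + split) / 2, split / 2),
    y = c((1 + split) / 2, (1 + split) / 2, split / 2, split / 2),
    label = c("attractive", "one-dimensional", "must-be", "indifferent"))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_hline(yintercept = split, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = split, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_text(data = corners, ggplot2::aes(label = label),
                       colour = "grey60", size = 3, fontface = "italic") +
    ggplot2::geom_point(ggplot2::aes(colour = classification), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = attr_id), vjust = -0.8, size = 2.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "|DS| (dissatisfaction impact)",
                  y = "CS (satisfaction impact)",
                  colour = "Kano class") +
    ggplot2::theme_minimal()
  if (facet) p <- p + ggplot2::facet_wrap(~dimension)
  p
}
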