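#' Histogram of pairwise AGMR values
#'
#' Mirrors the standard QC view: peaks near 0 are duplicate samples/MZ
#' twins, near 0.33 full siblings (or mislabelled DZ twins), near 0.39
#' parent-offspring and near 0.54 unrelated pairs.
#'
#' @param pairs A `kin_pairs` tibble (optionally classified).
#' @param binwidth Histogram bin width (default 0.005).
#' @return A ggplot object.
#' @export
plot_agmr_hist <- function(pairs, binwidth = 0.005) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$agmr))
  if ("relationship" %in% names(pairs))
    p <- p + ggplot2::aes(fill = .data$relationship)
  p + ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "AGMR (all genotype mismatch rate)", y = "pairs")
}

#' @rdname plot_agmr_hist
#' @export
plot_hgmr_hist <- function(pairs, binwidth = 0.005) {
  pairs <- pairs[!is.na(pairs$hgmr), ]
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$hgmr))
  if ("relationship" %in% names(pairs))
    p <- p + ggplot2::aes(fill = .data$relationship)
  p + ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "HGMR (homozygous genotype mismatch rate)",
                  y = "pairs")
}

#' Joint (HGMR, AGMR) scatter with decision boundaries
#'
#' @param pairs A `kin_pairs` tibble, typically after [classify_pairs()].
#' @param model Optional `kin_relmodel`; when supplied, the decision
#'   boundaries between adjacent relationship classes are drawn.
#' @return A ggplot object.
#' @export
plot_hgmr_agmr <- function(pairs, model = NULL) {
  pairs <- pairs[!is.na(pairs$hgmr), ]
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$hgmr, y = .data$agmr))
  if ("relationship" %in% names(pairs))
    p <- p + ggplot2::aes(colour = .data$relationship)
  p <- p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  if (!is.null(model)) {
    bl <- decision_boundaries(model,
                              xlim = range(0, pairs$hgmr),
                              ylim = range(pairs$agmr))
    if (nrow(bl))
      p <- p + ggplot2::geom_path(
        data = bl,
        ggplot2::aes(x = .data$hgmr, y = .data$agmr,
                     group = interaction(.data$boundary, .data$piece)),
        colour = "cyan3", inherit.aes = FALSE)
  }
  p + ggplot2::labs(x = "HGMR", y = "AGMR")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a `kin_pairs` tibble draws the joint (HGMR, AGMR)
#' scatter; on a `kin_relmodel` it draws the decision boundaries with the
#' class means.
#'
#' @param object A `kin_pairs` or `kin_relmodel` object.
#' @param ... Passed on (`model =` for `kin_pairs`).
#' @return A ggplot object.
#' @export
autoplot.kin_pairs <- function(object, ...) plot_hgmr_agmr(object, ...)

#' @rdname autoplot.kin_pairs
#' @export
autoplot.kin_relmodel <- function(object, ...) {
  bl <- decision_boundaries(object)
  p <- ggplot2::ggplot(bl, ggplot2::aes(
    x = .data$hgmr, y = .data$agmr,
    group = interaction(.data$boundary, .data$piece),
    colour = .data$boundary)) +
    ggplot2::geom_path()
  p + ggplot2::geom_point(
    data = object$params,
    ggplot2::aes(x = .data$mu_hgmr, y = .data$mu_agmr),
    inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::labs(x = "HGMR", y = "AGMR",
                  title = "Relationship decision boundaries")
}
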