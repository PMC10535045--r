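#' Histogram of per-key bit uniformity
#'
#' @param report A `library_report`.
#' @param bins Number of histogram bins.
#' @return A ggplot.
#' @export
plot_uniformity <- function(report, bins = 15) {
  ggplot2::ggplot(report$uniformity, ggplot2::aes(x = .data$uniformity)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "red3") +
    ggplot2::labs(x = "bit uniformity (fraction of 1-bits)", y = "keys",
                  title = sprintf("Bit uniformity: mean %.4f, median %.4f",
                                  report$uniformity_mean,
                                  report$uniformity_median)) +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise inter-device Hamming distances
#'
#' @inheritParams plot_uniformity
#' @return A ggplot.
#' @export
plot_inter_hd <- function(report, bins = 25) {
  ggplot2::ggplot(report$inter$pairs, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "red3") +
    ggplot2::labs(x = "normalized inter-Hamming distance", y = "pairs",
                  title = sprintf("Inter-HD: mean %.4f, sd %.4f (%d pairs)",
                                  report$inter$mean, report$inter$sd,
                                  report$inter$n_pairs)) +
    ggplot2::theme_minimal()
}

#' Genuine/impostor separation plot
#'
#' Overlaid percent-match distributions for genuine and impostor
#' comparisons, with the decision threshold.
#'
#' @param matches A tibble with columns `percent_match` and `genuine`
#'   (logical), e.g. from a capture-validation sweep.
#' @param threshold Accept threshold in percent.
#' @return A ggplot.
#' @export
plot_separation <- function(matches, threshold = 85) {
  ggplot2::ggplot(matches,
                  ggplot2::aes(x = .data$percent_match,
                               fill = ifelse(.data$genuine, "genuine",
                                             "impostor"))) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(genuine = "seagreen",
                                          impostor = "grey40"),
                               name = NULL) +
    ggplot2::labs(x = "percent match (biased vectors)", y = "comparisons") +
    ggplot2::theme_minimal()
}

#' Autoplot for library reports
#'
#' @param object A `library_report`.
#' @param type `"uniformity"` or `"inter_hd"`.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot.
#' @export
autoplot.library_report <- function(object, type = c("uniformity", "inter_hd"),
                                    ...) {
  type <- match.arg(type)
  switch(type,
         uniformity = plot_uniformity(object, ...),
         inter_hd = plot_inter_hd(object, ...))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Display an image with base graphics
#'
#' @param x An [aggregate_image()] or `binary_image`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.aggregate_image <- function(x, ...) {
  m <- unclass(x)
  graphics::image(t(m)[, rev(seq_len(nrow(m)))], col = gray.colors(256, 0, 1),
                  asp = 1, axes = FALSE, ...)
  invisible(x)
}

#' @rdname plot.aggregate_image
#' @export
plot.binary_image <- function(x, ...) {
  plot.aggregate_image(aggregate_image((1 - unclass(x)) * 255), ...)
}
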