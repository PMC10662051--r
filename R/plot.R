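#' Plot a segmented track
#'
#' Position--time trace overlaid with the piecewise-linear segmentation,
#' coloured by segment kind (positive runs, negative runs, pauses).
#'
#' @param object A `tug_segments` object from [segment_track()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tug_segments
#' @export
autoplot.tug_segments <- function(object, ...) {
  track <- attr(object, "track")
  segs <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$t_s,
                                           y = .data$x_nm / 1000)) +
    ggplot2::geom_point(colour = "grey60", size = 0.5)
  p + ggplot2::geom_segment(
    data = segs,
    ggplot2::aes(x = .data$t_start, xend = .data$t_end,
                 y = .data$x_start / 1000, yend = .data$x_end / 1000,
                 colour = .data$kind), linewidth = 1) +
    ggplot2::scale_colour_manual(values = c(run_pos = "#2e8b57",
                                            run_neg = "#1f6fb4",
                                            pause = "#888888")) +
    ggplot2::labs(x = "time (s)", y = "position (µm)",
                  colour = "segment")
}

#' @export
plot.tug_segments <- function(x, ...) print(autoplot.tug_segments(x, ...))

#' Stacked bar chart of track-class fractions
#'
#' @param fractions Either a [class_fractions()] tibble for one condition
#'   or a tibble with an extra `condition` column for several.
#' @return A ggplot object.
#' @export
plot_class_fractions <- function(fractions) {
  if (!"condition" %in% names(fractions)) fractions$condition <- "all"
  fractions$label <- factor(fractions$label,
                            levels = c("minus", "reversal", "plus",
                                       "stationary"))
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$condition, y = .data$fraction,
                               fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(minus = "#1f6fb4",
                                          reversal = "#c2399b",
                                          plus = "#2e8b57",
                                          stationary = "#b7a6d4")) +
    ggplot2::labs(x = NULL, y = "fraction of tracks", fill = "track class")
}
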