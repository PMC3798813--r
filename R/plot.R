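# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   facet_wrap labs scale_y_log10 scale_x_log10 theme_minimal geom_col
#' @export
ggplot2::autoplot

#' Plot a tracked length series
#' @param object a `length_series` tibble from [spring_length()].
#' @param truth optional `ground_truth` whose imposed length is overlaid.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.length_series <- function(object, truth = NULL, ...) {
  g <- ggplot(object, aes(x = .data$time_s, y = .data$length_mm)) +
    geom_line(colour = "#2c7fb8") +
    labs(x = "time (s)", y = "spring length (mm)",
         title = "Tracked spring length") +
    theme_minimal()
  if (!is.null(truth))
    g <- g + geom_line(data = truth$track,
                       aes(x = .data$time_s, y = .data$length_mm),
                       linetype = "dashed", colour = "grey40")
  g
}

#' Plot twitch series
#' @param object a `twitch_series` tibble.
#' @param ... ignored.
#' @return a ggplot object with one facet per measure.
#' @export
autoplot.twitch_series <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("fascicle_length_mm", "thickness_mm"),
                              names_to = "measure", values_to = "mm")
  ggplot(long, aes(x = .data$time_s, y = .data$mm)) +
    geom_line(colour = "#2c7fb8") +
    facet_wrap(~measure, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = "mm", title = "Twitch kinematics") +
    theme_minimal()
}

#' Plot a per-channel NMSE map over the electrode grid
#' @param object an `nmse_map` from [template_nmse_map()].
#' @param ... ignored.
#' @return a ggplot tile map (rows proximal at the top).
#' @export
autoplot.nmse_map <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$col), y = factor(-.data$row),
                     fill = .data$nmse_pct)) +
    geom_tile(colour = "white") +
    labs(x = "column", y = "row", fill = "NMSE (%)",
         title = "M-wave template NMSE over the grid") +
    theme_minimal()
}

#' Plot an impedance spectrum (magnitude and phase vs frequency)
#' @param object an `impedance_spectrum` tibble.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.impedance_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("magnitude_ohm", "phase_deg"),
                              names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$frequency_hz, y = .data$value)) +
    geom_line() + geom_point() +
    scale_x_log10() +
    facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    labs(x = "frequency (Hz)", y = NULL,
         title = "Electrode-skin impedance spectrum") +
    theme_minimal()
}

#' Plot an average intensity histogram
#' @param object an `intensity_report` from [roi_intensity()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.intensity_report <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$intensity, y = .data$mean_count)) +
    geom_col(width = 1, fill = "#2c7fb8") +
    labs(x = "intensity (8-bit level)", y = "mean pixel count",
         title = "Average ROI intensity histogram") +
    theme_minimal()
}
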