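# ggplot2 views of the result types. Each autoplot() returns a plot the
# caller can restyle; nothing is drawn as a side effect.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_raster geom_col geom_errorbar labs scale_fill_gradient
#'   scale_fill_manual theme_minimal coord_fixed
#' @export
ggplot2::autoplot

#' Plot a radial profile
#'
#' Intensity versus radial distance, the signal every ring readout is taken
#' from.
#'
#' @param object A [radial_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, ...) {
  agg <- profile_aggregation(object)
  ggplot(tidy(object), aes(x = .data$radius_um, y = .data$value)) +
    geom_line(colour = "#2c7fb8") +
    labs(
      x = "radial distance (µm)",
      y = sprintf("%s intensity per bin (AU)", agg),
      title = "Radial intensity profile"
    ) +
    theme_minimal()
}

#' Plot an image frame
#'
#' Raster view of a calibrated frame with physical axes in micrometres.
#'
#' @param object An [image_frame()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.image_frame <- function(object, ...) {
  mpp <- frame_calibration(object)
  df <- expand.grid(
    y_um = (seq_len(nrow(object)) - 0.5) * mpp,
    x_um = (seq_len(ncol(object)) - 0.5) * mpp
  )
  df$intensity <- as.vector(as_plain_matrix(object))
  ggplot(df, aes(x = .data$x_um, y = .data$y_um, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "#7CFC00") +
    coord_fixed() +
    labs(x = "x (µm)", y = "y (µm)", fill = "AU") +
    theme_minimal()
}

#' Plot a network mask
#'
#' @param object A `network_mask` from [binarize()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.network_mask <- function(object, ...) {
  mpp <- attr(object, "microns_per_pixel")
  df <- expand.grid(
    y_um = (seq_len(nrow(object)) - 0.5) * mpp,
    x_um = (seq_len(ncol(object)) - 0.5) * mpp
  )
  df$foreground <- as.vector(unclass(object))
  ggplot(df, aes(x = .data$x_um, y = .data$y_um, fill = .data$foreground)) +
    geom_raster() +
    scale_fill_manual(values = c(`FALSE` = "black", `TRUE` = "white")) +
    coord_fixed() +
    labs(x = "x (µm)", y = "y (µm)", fill = "mask") +
    theme_minimal()
}

#' Plot an area timecourse
#'
#' Relative network area per day with the baseline level marked.
#'
#' @param object An `area_timecourse` from [relative_growth()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.area_timecourse <- function(object, ...) {
  baseline <- if (attr(object, "convention") == "percent_of_baseline") 100 else 0
  ggplot(object, aes(x = .data$day, y = .data$relative_growth_percent)) +
    geom_hline(yintercept = baseline, linetype = "dashed", colour = "grey50") +
    geom_line(colour = "#2c7fb8") +
    geom_point() +
    labs(x = "day", y = "network area (% of baseline)",
         title = "Network area relative to baseline day") +
    theme_minimal()
}

#' Plot Dunnett comparisons
#'
#' Per-group effect estimates versus the control with significance stars.
#'
#' @param object A `dunnett_fit` from [dunnett_test()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dunnett_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$group, y = .data$estimate)) +
    geom_col(fill = "#2c7fb8") +
    geom_point(aes(y = .data$estimate)) +
    labs(
      x = NULL, y = sprintf("difference vs %s", object$control),
      title = "Dunnett many-to-one comparisons",
      subtitle = paste(df$group, df$stars, collapse = "   ")
    ) +
    theme_minimal()
}
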