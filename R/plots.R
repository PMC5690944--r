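# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial NPS profile
#'
#' @param object an [nps_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nps_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = expression(paste("spatial frequency (", mm^-1, ")")),
      y = expression(paste("NPS (", HU^2 * mm^2, ")")),
      title = "Radial noise power spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a fitted NPS model over the measured profile
#'
#' @param object an `nps_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nps_fit <- function(object, ...) {
  df <- tibble::tibble(frequency = object$profile$frequency,
                       measured = object$profile$power,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured),
                        size = 0.8, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(
      x = expression(paste("spatial frequency (", mm^-1, ")")),
      y = expression(paste("NPS (", HU^2 * mm^2, ")")),
      title = "Measured NPS and parametric fit") +
    ggplot2::theme_minimal()
}

#' Histogram of a registration error map
#'
#' @param error_map numeric array of per-voxel errors (mm); `NA`s dropped.
#' @param threshold reference threshold drawn as a vertical line, mm.
#' @param bins histogram bin count.
#' @return a ggplot.
#' @export
plot_error_histogram <- function(error_map, threshold = 2, bins = 60) {
  df <- tibble::tibble(error = as.numeric(error_map))
  df <- df[!is.na(df$error), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "registration error (mm)", y = "voxels",
                  title = "Registration error distribution") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
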