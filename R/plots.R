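# ggplot2 visualization methods. Beam patterns are drawn in the
# azimuth-elevation plane with the -3 dB main-lobe contour overlaid;
# steering curves and comparison reports get simple dedicated plots.

#' Plot a beam pattern
#'
#' Raster of normalized energy over azimuth and elevation, faceted by
#' frequency, with the main-lobe contour overlaid.
#'
#' @param object A `beam_pattern`.
#' @param frequencies Frequencies to show (default: all).
#' @param contour_level Contour level, dB (default -3).
#' @param zoom Optional `c(az, el)` half-widths to crop the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beam_pattern
#' @export
autoplot.beam_pattern <- function(object, frequencies = object$frequency,
                                  contour_level = -3, zoom = NULL, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$frequency %in% frequencies) |>
    dplyr::mutate(frequency_khz = factor(.data$frequency / 1e3))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$azimuth, .data$elevation)) +
    ggplot2::geom_raster(ggplot2::aes(fill = pmax(.data$db, -40))) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$db),
                          breaks = contour_level, colour = "white",
                          linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "dB", limits = c(-40, 0)) +
    ggplot2::facet_wrap(~frequency_khz, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth (deg, + left)", y = "elevation (deg, + dorsal)")
  if (!is.null(zoom)) {
    p <- p + ggplot2::coord_fixed(xlim = c(-zoom[1], zoom[1]),
                                  ylim = c(-zoom[2], zoom[2]))
  }
  p
}

#' Plot a tongue-steering curve
#'
#' @param object A `steering_curve` from [steering_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot steering_curve
#' @export
autoplot.steering_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$displacement, .data$center_azimuth)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "tongue displacement (mm)",
                  y = "beam-center azimuth (deg)")
}

#' Plot a model-comparison report
#'
#' Aspect-ratio distributions of the per-click -3 dB ellipses by source.
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  ggplot2::ggplot(object$features,
                  ggplot2::aes(.data$source, .data$aspect_ratio)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "aspect ratio (elevation / azimuth extent)")
}

#' Plot the average beams of a reconstructed session
#'
#' @param object A `session_recon`.
#' @param frequency Frequency to show, Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot session_recon
#' @export
autoplot.session_recon <- function(object, frequency = object$ref_frequency,
                                   ...) {
  df <- purrr::imap(object$beams, function(b, sd) {
    tidy(b) |> dplyr::filter(.data$frequency == !!frequency) |>
      dplyr::mutate(side = sd)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$azimuth, .data$elevation)) +
    ggplot2::geom_raster(ggplot2::aes(fill = pmax(.data$db, -40))) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$db), breaks = -3,
                          colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "dB", limits = c(-40, 0)) +
    ggplot2::facet_wrap(~side) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth (deg, + left)", y = "elevation (deg, + dorsal)")
}
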