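# ggplot2 views of spectra, metric spectra and topographies.

#' Plot an amplitude spectrum
#'
#' @param object An `fpvs_spectrum`.
#' @param channels Channels to draw (default all).
#' @param max_freq Upper frequency limit of the plot in Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fpvs_spectrum
#' @export
autoplot.fpvs_spectrum <- function(object, channels = object$channel_labels,
                                   max_freq = 12, ...) {
  df <- tidy.fpvs_spectrum(object) |>
    dplyr::filter(.data$channel %in% channels,
                  .data$frequency <= max_freq)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a metric (SNR or Z-score) spectrum
#'
#' Draws the metric across frequency with a horizontal reference at the
#' noise level (SNR = 1) or the one-tailed significance criterion
#' (Z = 1.64).
#'
#' @param object An `fpvs_metric`.
#' @param channels Channels to draw (default all).
#' @param max_freq Upper frequency limit (Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fpvs_metric
#' @export
autoplot.fpvs_metric <- function(object, channels = object$channel_labels,
                                 max_freq = 12, ...) {
  df <- tidy.fpvs_metric(object) |>
    dplyr::filter(.data$channel %in% channels,
                  .data$frequency <= max_freq, .data$defined)
  ref <- if (object$metric == "snr") 1 else 1.64
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$value)) +
    ggplot2::geom_hline(yintercept = ref, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = if (object$metric == "snr") "SNR" else "Z-score") +
    ggplot2::theme_minimal()
}

#' Plot a scalp topography table
#'
#' Simple top-view scatter map of per-channel values (no interpolation;
#' the tabular export is the deliverable, this is a convenience view).
#'
#' @param topo A tibble from [topography_table()].
#' @param label Draw channel labels (default TRUE).
#' @return A ggplot object.
#' @export
plot_topography <- function(topo, label = TRUE) {
  p <- ggplot2::ggplot(topo, ggplot2::aes(.data$x, .data$y,
                                          colour = .data$value)) +
    ggplot2::geom_point(size = 6) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "value") +
    ggplot2::theme_void()
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$channel),
                                vjust = -1.2, size = 3, colour = "black")
  }
  p
}
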