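# ggplot2 methods for the result types. These are presentation defaults; all
# underlying numbers are available through tidy() and the tibbles themselves.

#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_boxplot labs
#'   scale_y_log10 scale_x_log10 scale_fill_viridis_c theme_minimal
NULL

#' Plot a PSD grid as a spectrogram
#'
#' @param object A `psd_grid`.
#' @param log_frequency Use a log10 frequency axis (drops the 0 Hz bin).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psd_grid <- function(object, log_frequency = FALSE, ...) {
  d <- tidy(object)
  if (log_frequency) d <- d[d$frequency > 0, ]
  gg <- ggplot(d, aes(x = .data$time, y = .data$frequency,
                      fill = .data$level)) +
    geom_raster() +
    scale_fill_viridis_c(name = sprintf("dB re %g uPa²/Hz",
                                        object$p_ref^2)) +
    labs(x = "Time", y = "Frequency (Hz)") +
    theme_minimal()
  if (log_frequency) gg <- gg + scale_y_log10()
  gg
}

#' Plot band level time series
#'
#' @param object A `band_series` from [third_octave_levels()].
#' @param ... Unused.
#' @return A ggplot with one line per nominal band.
#' @export
autoplot.band_series <- function(object, ...) {
  p_ref <- attr(object, "p_ref") %||% 1
  ggplot(object, aes(x = .data$time, y = .data$level,
                     colour = factor(.data$nominal))) +
    geom_line() +
    labs(x = "Time", y = sprintf("Level (dB re %g uPa)", p_ref),
         colour = "Band (Hz)") +
    theme_minimal()
}

#' Plot a spectral probability density
#'
#' @param object An `spd` from [spd()].
#' @param log_frequency Log10 frequency axis (drops 0 Hz).
#' @param ... Unused.
#' @return A ggplot raster of density over (frequency, level).
#' @export
autoplot.spd <- function(object, log_frequency = TRUE, ...) {
  d <- object
  if (log_frequency) d <- d[d$frequency > 0, ]
  gg <- ggplot(d, aes(x = .data$frequency, y = .data$level,
                      fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c(name = "Density (1/dB)") +
    labs(x = "Frequency (Hz)", y = "PSD level (dB)") +
    theme_minimal()
  if (log_frequency) gg <- gg + scale_x_log10()
  gg
}

#' Composite percentile/average spectrum plot
#'
#' The classic habitat summary: per-frequency percentile levels with the RMS
#' average, median and mode overlaid, computed from a stored PSD grid alone.
#'
#' @param grid A `psd_grid`.
#' @param probs Percentiles to draw.
#' @param bin_width Mode histogram bin width (dB).
#' @return A ggplot.
#' @export
plot_spectrum_stats <- function(grid, probs = c(1, 5, 50, 95, 99),
                                bin_width = 1) {
  st <- spectrum_stats(grid, probs = probs, bin_width = bin_width)
  long <- tidyr::pivot_longer(
    st[, c("frequency", "rms_level", "median", "mode",
           paste0("p", probs))],
    -"frequency", names_to = "statistic", values_to = "level"
  )
  ggplot(long[long$frequency > 0, ],
         aes(x = .data$frequency, y = .data$level,
             colour = .data$statistic)) +
    geom_line() +
    scale_x_log10() +
    labs(x = "Frequency (Hz)",
         y = sprintf("PSD level (dB re %g uPa²/Hz)", grid$p_ref^2)) +
    theme_minimal()
}
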