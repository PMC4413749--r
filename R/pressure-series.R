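#' Calibrated pressure waveform
#'
#' A `pressure_series` is an absolute sound-pressure waveform in micropascals
#' with sampling metadata and the decibel reference pressure of its domain
#' (20 uPa in air, 1 uPa underwater). It is produced by
#' [apply_calibration()] or by the synthetic generators, and consumed by the
#' spectral, statistical and impulse analyses.
#'
#' @param pressure Numeric vector, sound pressure in micropascals.
#' @param sample_rate Sampling rate in Hz.
#' @param start_time `POSIXct` or offset seconds.
#' @param p_ref Reference pressure in micropascals (20 in air, 1 in water).
#' @param clipped_fraction Fraction of source samples that were saturated.
#' @return An object of class `pressure_series`.
#' @export
pressure_series <- function(pressure, sample_rate, start_time = 0,
                            p_ref = 1, clipped_fraction = 0) {
  if (!is.numeric(pressure)) abort("`pressure` must be numeric.")
  if (any(!is.finite(pressure))) abort("`pressure` must be finite everywhere.")
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  stopifnot_scalar(p_ref, "p_ref", positive = TRUE)
  structure(
    list(
      pressure = as.numeric(pressure),
      sample_rate = sample_rate,
      start_time = start_time,
      p_ref = p_ref,
      clipped_fraction = clipped_fraction
    ),
    class = "pressure_series"
  )
}

#' @export
print.pressure_series <- function(x, ...) {
  cat(sprintf(
    "<pressure_series> %d samples @ %g Hz (%.3f s), p_ref = %g uPa\n",
    length(x$pressure), x$sample_rate, duration(x), x$p_ref
  ))
  cat(sprintf(
    "  start: %s | RMS level: %.2f dB re %g uPa | clipped: %.4g%%\n",
    format(x$start_time), spl_rms(x), x$p_ref, 100 * x$clipped_fraction
  ))
  invisible(x)
}

#' @export
length.pressure_series <- function(x) length(x$pressure)

#' Duration of a pressure series in seconds
#' @param p A [pressure_series()].
#' @return Length in seconds.
#' @export
duration <- function(p) {
  stopifnot(inherits(p, "pressure_series"))
  length(p$pressure) / p$sample_rate
}

# 1-based sample index range for a [t0, t1) time window (offset seconds)
window_indices <- function(p, t0, t1) {
  if (!(t0 >= 0 && t1 > t0 && t0 < duration(p))) {
    abort("Time window must satisfy 0 <= t0 < t1 and lie within the series.")
  }
  i0 <- floor(t0 * p$sample_rate) + 1L
  i1 <- min(ceiling(t1 * p$sample_rate), length(p$pressure))
  if (i1 < i0) abort("Time window contains no samples.")
  seq.int(i0, i1)
}

#' Time-domain RMS sound pressure level
#'
#' The broadband RMS level of a (windowed) pressure waveform:
#' `20 * log10(rms(p) / p_ref)` in dB re `p_ref`.
#'
#' @param p A [pressure_series()].
#' @param t0,t1 Optional window in offset seconds (default the whole series).
#' @return Level in dB re `p_ref`.
#' @export
spl_rms <- function(p, t0 = 0, t1 = duration(p)) {
  idx <- window_indices(p, t0, t1)
  x <- p$pressure[idx]
  if (all(x == 0)) abort("RMS level is undefined for an all-zero window.")
  10 * log10(mean(x^2) / p$p_ref^2)
}
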