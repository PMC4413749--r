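# Waveform-domain metrics for impulsive events (airgun pulses, pile strikes,
# echolocation clicks). Frequency spectra misrepresent impulse amplitudes, so
# peaks, pulse energy and duration are measured on the pressure waveform at
# full time resolution.

check_window <- function(p, window, name = "window") {
  if (!(is.numeric(window) && length(window) == 2L && window[2L] > window[1L])) {
    abort(sprintf("`%s` must be c(t0, t1) with t1 > t0.", name))
  }
  window_indices(p, window[1L], window[2L])
}

#' Peak sound pressure levels of a pulse
#'
#' Zero-to-peak and peak-to-peak pressure levels over a time window:
#' `SPL_0p = 20*log10(max|p| / p_ref)` and
#' `SPL_pp = 20*log10((max p - min p) / p_ref)`. For a symmetric waveform
#' the two differ by `20*log10(2)` (about 6.02 dB); `SPL_pp` never exceeds
#' `SPL_0p` by more than that.
#'
#' @param p A [pressure_series()].
#' @param window `c(t0, t1)` in offset seconds.
#' @return A one-row tibble with `spl_zero_to_peak` and `spl_peak_to_peak`
#'   (dB re p_ref).
#' @export
peak_levels <- function(p, window = c(0, duration(p))) {
  idx <- check_window(p, window)
  x <- p$pressure[idx]
  if (all(x == 0)) abort("Peak level is undefined for an all-zero window.")
  tibble::tibble(
    spl_zero_to_peak = 20 * log10(max(abs(x)) / p$p_ref),
    spl_peak_to_peak = 20 * log10((max(x) - min(x)) / p$p_ref)
  )
}

#' 90% energy envelope of a pulse
#'
#' Pulse duration is conventionally the 90% energy envelope: the interval
#' between 5% and 95% of the cumulative acoustic energy
#' `E(t) = sum(p^2 * dt)`. Threshold crossings take the first sample at or
#' above the threshold (no sub-sample interpolation; bias under one sample
#' period), so the energy fraction inside the envelope is at least
#' `hi - lo` by construction.
#'
#' @inheritParams peak_levels
#' @param lo,hi Cumulative-energy fractions bounding the envelope
#'   (defaults 0.05 and 0.95).
#' @return A one-row tibble: `t5`, `t95` (offset seconds), `tau90`
#'   (`t95 - t5`), `sel_in_envelope` (dB re p_ref^2 s) and
#'   `energy_fraction` (energy inside the envelope over total).
#' @export
energy_envelope <- function(p, window = c(0, duration(p)),
                            lo = 0.05, hi = 0.95) {
  if (!(is_scalar_number(lo) && is_scalar_number(hi) &&
        lo >= 0 && hi <= 1 && lo < hi)) {
    abort("Need 0 <= lo < hi <= 1.")
  }
  idx <- check_window(p, window)
  x <- p$pressure[idx]
  dt <- 1 / p$sample_rate
  e <- cumsum(x^2) * dt
  e_tot <- e[length(e)]
  if (e_tot <= 0) abort("Energy envelope is undefined for zero total energy.")
  i5 <- which(e >= lo * e_tot)[1L]
  i95 <- which(e >= hi * e_tot)[1L]
  t0 <- window[1L]
  t5 <- t0 + (i5 - 1L) * dt
  if (i95 <= i5) i95 <- i5 + 1L # degenerate single-sample pulse
  frac <- (e[i95] - if (i5 > 1L) e[i5 - 1L] else 0) / e_tot
  tibble::tibble(
    t5 = t5,
    t95 = t0 + (i95 - 1L) * dt,
    tau90 = (i95 - i5) * dt,
    sel_in_envelope = 10 * log10(
      (e[i95] - if (i5 > 1L) e[i5 - 1L] else 0) / p$p_ref^2
    ),
    energy_fraction = frac
  )
}

#' Sound exposure level of a pulse window
#'
#' The acoustic energy contained in the pulse: [sel()] restricted to the
#' pulse window (identical definition).
#'
#' @inheritParams peak_levels
#' @return SEL in dB re p_ref^2 s.
#' @export
pulse_sel <- function(p, window = c(0, duration(p))) {
  check_window(p, window)
  sel(p, window[1L], window[2L])
}

#' Signal-to-noise ratio check for pulse measurements
#'
#' Pulse metrics are only reliable when the pulse stands well clear of the
#' background: the SNR — RMS level of the pulse window minus RMS level of a
#' disjoint noise window, in dB — should be at least 10 dB.
#'
#' @inheritParams peak_levels
#' @param pulse_window,noise_window Disjoint `c(t0, t1)` windows in offset
#'   seconds.
#' @param threshold Validity threshold in dB (default 10).
#' @return A one-row tibble with `snr` (dB) and `valid`
#'   (`snr >= threshold`).
#' @export
snr_check <- function(p, pulse_window, noise_window, threshold = 10) {
  check_window(p, pulse_window, "pulse_window")
  check_window(p, noise_window, "noise_window")
  if (pulse_window[1L] < noise_window[2L] &&
      noise_window[1L] < pulse_window[2L]) {
    abort("`pulse_window` and `noise_window` must be disjoint.")
  }
  snr <- spl_rms(p, pulse_window[1L], pulse_window[2L]) -
    spl_rms(p, noise_window[1L], noise_window[2L])
  tibble::tibble(snr = snr, valid = snr >= threshold)
}

#' All waveform metrics for one impulsive event
#'
#' Bundles [peak_levels()], [pulse_sel()], [energy_envelope()] and (when a
#' noise window is given) [snr_check()] into one row per event. Pulse SEL is
#' reported both over the full window (`sel_pulse`) and within the 90%
#' envelope (`sel_in_envelope`). If a calibration spec with a frequency
#' response is supplied, a warning is raised when the system response varies
#' by more than 3 dB across the pulse's -10 dB spectral extent — peak
#' metrics are then biased by the system's frequency shaping.
#'
#' @inheritParams snr_check
#' @param noise_window Optional disjoint background window; without it `snr`
#'   and `valid` are `NA`.
#' @param cal Optional [cal_spec()] used only for the response-flatness
#'   check.
#' @inheritParams energy_envelope
#' @return A one-row tibble with `spl_zero_to_peak`, `spl_peak_to_peak`,
#'   `sel_pulse`, `t5`, `t95`, `tau90`, `sel_in_envelope`, `snr`, `valid`.
#' @export
pulse_metrics <- function(p, pulse_window = c(0, duration(p)),
                          noise_window = NULL, threshold = 10,
                          lo = 0.05, hi = 0.95, cal = NULL) {
  pk <- peak_levels(p, pulse_window)
  env <- energy_envelope(p, pulse_window, lo, hi)
  qc <- if (!is.null(noise_window)) {
    snr_check(p, pulse_window, noise_window, threshold)
  } else {
    tibble::tibble(snr = NA_real_, valid = NA)
  }
  if (!is.null(cal) && !is.null(cal$frequency_response)) {
    check_response_flatness(p, pulse_window, cal)
  }
  dplyr::bind_cols(
    tibble::tibble(t_start = pulse_window[1L], t_end = pulse_window[2L]),
    pk,
    tibble::tibble(sel_pulse = pulse_sel(p, pulse_window)),
    env[, c("t5", "t95", "tau90", "sel_in_envelope")],
    qc
  )
}

# warn when the system response varies > 3 dB across the pulse's -10 dB
# spectral extent (the band around the spectral peak within 10 dB of it)
check_response_flatness <- function(p, window, cal, tol_db = 3) {
  idx <- check_window(p, window)
  x <- p$pressure[idx]
  n <- length(x)
  spec <- Mod(fft(x))[seq_len(n %/% 2 + 1)]
  freqs <- (seq_len(n %/% 2 + 1) - 1) * p$sample_rate / n
  lev <- 20 * log10(pmax(spec, .Machine$double.xmin))
  peak <- max(lev)
  in_extent <- which(lev >= peak - 10)
  f_band <- range(freqs[in_extent])
  corr <- frequency_response_at(cal, freqs[in_extent])
  spread <- diff(range(corr))
  if (spread > tol_db) {
    warn(sprintf(
      "System response varies %.1f dB across the pulse's -10 dB spectral extent (%.0f-%.0f Hz); peak metrics may be biased.",
      spread, f_band[1L], f_band[2L]
    ))
  }
  invisible(spread)
}
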