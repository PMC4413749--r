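# Welch/STFT engine. All spectra are single-sided power spectral densities
# with window compensation by sum(w^2): for segment x and taper w,
#   P[k] = |FFT(w*x)[k]|^2 / (fs * sum(w^2)),  doubled except at DC/Nyquist,
# so that sum(P * df) equals the (windowed) mean-square pressure and white
# noise of variance s^2 has density s^2/(fs/2).

#' Welch-averaged power spectral density grid
#'
#' Splits a calibrated pressure waveform into (optionally overlapping)
#' windowed segments, computes the single-sided, window-compensated
#' periodogram of each, and averages periodograms arithmetically within
#' consecutive intervals of `average_seconds` (the Welch method). With
#' `average_seconds = NULL` every segment becomes one output column (a
#' spectrogram; see [spectrogram()]).
#'
#' @param p A [pressure_series()].
#' @param segment_length Segment (FFT) length N in samples; alternatively
#'   give `segment_seconds`.
#' @param segment_seconds Segment length in seconds (converted to samples).
#' @param window Taper kind, see [window_coefficients()]. Default `"hann"`.
#' @param overlap Fractional overlap between successive segments in
#'   \[0, 1); default 0.5.
#' @param average_seconds Welch output resolution in seconds (must be at
#'   least one segment duration), or `NULL` for one column per segment.
#' @return A `psd_grid`: levels matrix (frequency x time) in dB re
#'   p_ref^2/Hz, with `frequencies` (Hz, 0 to Nyquist, spacing
#'   `sample_rate/N`), `times` (segment/interval centres, offset seconds),
#'   `n_segments` averaged per column, and the analysis configuration.
#' @seealso [spectrogram()], [third_octave_levels()], [broadband_spl()],
#'   [spd()]
#' @export
#' @examples
#' p <- synth_white_noise(60, duration = 10, sample_rate = 2000, seed = 1)
#' g <- psd_welch(p, segment_seconds = 1, average_seconds = 10)
#' dim(g$levels)
psd_welch <- function(p, segment_length = NULL, segment_seconds = NULL,
                      window = "hann", overlap = 0.5,
                      average_seconds = NULL) {
  stopifnot(inherits(p, "pressure_series"))
  fs <- p$sample_rate
  if (is.null(segment_length)) {
    if (is.null(segment_seconds)) {
      abort("Give `segment_length` (samples) or `segment_seconds`.")
    }
    segment_length <- round(segment_seconds * fs)
  }
  n_seg <- as.integer(segment_length)
  if (n_seg < 2L) abort("`segment_length` must be >= 2 samples.")
  if (!is_scalar_number(overlap) || overlap < 0 || overlap >= 1) {
    abort("`overlap` must be in [0, 1).")
  }
  L <- length(p$pressure)
  if (L < n_seg) {
    abort(sprintf(
      "Series has %d samples but one segment needs %d.", L, n_seg
    ))
  }
  if (!is.null(average_seconds)) {
    stopifnot_scalar(average_seconds, "average_seconds", positive = TRUE)
    if (average_seconds < n_seg / fs - 1e-9) {
      abort("`average_seconds` must be at least one segment duration.")
    }
  }
  wc <- window_coefficients(window, n_seg)
  hop <- max(1L, as.integer(round(n_seg * (1 - overlap))))
  starts <- seq.int(1L, L - n_seg + 1L, by = hop)
  idx <- outer(seq_len(n_seg) - 1L, starts, `+`)
  xm <- matrix(p$pressure[idx], nrow = n_seg) * wc$w
  sp <- mvfft(xm)
  n_freq <- n_seg %/% 2L + 1L
  pw <- (Mod(sp[seq_len(n_freq), , drop = FALSE])^2) / (fs * sum(wc$w^2))
  dbl <- rep(2, n_freq)
  dbl[1L] <- 1
  if (n_seg %% 2L == 0L) dbl[n_freq] <- 1
  pw <- pw * dbl
  centers <- (starts - 1 + n_seg / 2) / fs

  if (is.null(average_seconds)) {
    power <- pw
    times <- centers
    n_avg <- rep(1L, length(starts))
  } else {
    group <- floor((starts - 1) / fs / average_seconds)
    ug <- sort(unique(group))
    power <- vapply(ug, function(g) {
      rowMeans(pw[, group == g, drop = FALSE])
    }, numeric(n_freq))
    power <- matrix(power, nrow = n_freq)
    times <- (ug + 0.5) * average_seconds
    n_avg <- vapply(ug, function(g) sum(group == g), integer(1L))
  }

  new_psd_grid(
    levels = 10 * log10(pmax(power, .Machine$double.xmin) / p$p_ref^2),
    frequencies = (seq_len(n_freq) - 1L) * fs / n_seg,
    times = times,
    p = p,
    config = list(
      window = window, segment_length = n_seg, overlap = overlap,
      average_seconds = average_seconds, scaling = "density"
    ),
    n_segments = n_avg
  )
}

new_psd_grid <- function(levels, frequencies, times, p, config, n_segments) {
  structure(
    list(
      levels = levels,
      frequencies = frequencies,
      times = times,
      start_time = p$start_time,
      sample_rate = p$sample_rate,
      p_ref = p$p_ref,
      clipped_fraction = p$clipped_fraction,
      config = config,
      n_segments = n_segments
    ),
    class = "psd_grid"
  )
}

#' @export
print.psd_grid <- function(x, ...) {
  cat(sprintf(
    "<psd_grid> %d frequencies (0-%g Hz, df = %g Hz) x %d time steps\n",
    length(x$frequencies), max(x$frequencies),
    x$frequencies[2L] - x$frequencies[1L], length(x$times)
  ))
  cat(sprintf(
    "  dB re %g uPa^2/Hz | %s window, N = %d, overlap = %g%s\n",
    x$p_ref^2, x$config$window, x$config$segment_length, x$config$overlap,
    if (!is.null(x$config$average_seconds)) {
      sprintf(", Welch-averaged to %g s", x$config$average_seconds)
    } else ""
  ))
  invisible(x)
}

#' Spectrogram (unaveraged PSD time series)
#'
#' [psd_welch()] with no time averaging: one calibrated PSD column per
#' windowed segment, honouring the overlap. High overlap (e.g. 0.99) smooths
#' the time dimension for impulse inspection.
#'
#' @inheritParams psd_welch
#' @return A `psd_grid` with one column per segment.
#' @export
spectrogram <- function(p, segment_length = NULL, segment_seconds = NULL,
                        window = "hann", overlap = 0.5) {
  psd_welch(p, segment_length = segment_length,
            segment_seconds = segment_seconds, window = window,
            overlap = overlap, average_seconds = NULL)
}

# linear band power (uPa^2) per time step from a psd_grid; bins belong to a
# band when their centre frequency lies inside [f_lo, f_hi]
band_power <- function(grid, f_lo, f_hi) {
  df <- grid$sample_rate / grid$config$segment_length
  sel <- grid$frequencies >= f_lo & grid$frequencies <= f_hi
  if (!any(sel)) {
    abort(sprintf("No PSD bins between %g and %g Hz.", f_lo, f_hi))
  }
  pw <- undb(grid$levels[sel, , drop = FALSE]) * grid$p_ref^2
  colSums(pw) * df
}

#' Band sound pressure level from a PSD grid
#'
#' Integrates PSD power over `[f_lo, f_hi]` per time step and converts to a
#' level: `10*log10(sum(P*df) / p_ref^2)`. Bin membership is by bin centre.
#'
#' @param grid A `psd_grid` from [psd_welch()] or [spectrogram()].
#' @param f_lo,f_hi Band edges in Hz (`0 <= f_lo < f_hi <= ` Nyquist).
#' @return A tibble with columns `time` (centre, offset seconds or `POSIXct`
#'   if the grid has an absolute start) and `spl` (dB re p_ref).
#' @export
band_spl <- function(grid, f_lo = 0, f_hi = max(grid$frequencies)) {
  stopifnot(inherits(grid, "psd_grid"))
  if (!(f_lo >= 0 && f_hi > f_lo && f_hi <= max(grid$frequencies) + 1e-9)) {
    abort("Need 0 <= f_lo < f_hi <= Nyquist.")
  }
  tibble::tibble(
    time = grid_times(grid),
    spl = 10 * log10(band_power(grid, f_lo, f_hi) / grid$p_ref^2)
  )
}

#' Broadband (or band-limited) SPL time series from a waveform
#'
#' Convenience wrapper: runs [psd_welch()] and integrates the requested band
#' per time step. Over the full band this equals the time-domain RMS level
#' (exactly so for the rectangular window, by Parseval's theorem).
#'
#' @inheritParams psd_welch
#' @param f_lo,f_hi Band limits in Hz; defaults to the full band up to
#'   Nyquist.
#' @return A tibble with `time` and `spl` (dB re p_ref) columns.
#' @export
#' @examples
#' p <- synth_tone(1000, spl = 100, duration = 2, sample_rate = 8000)
#' broadband_spl(p, segment_seconds = 1)$spl # ~100 dB
broadband_spl <- function(p, f_lo = 0, f_hi = p$sample_rate / 2,
                          segment_length = NULL, segment_seconds = NULL,
                          window = "hann", overlap = 0.5,
                          average_seconds = NULL) {
  if (is.null(segment_length) && is.null(segment_seconds)) {
    segment_seconds <- min(1, duration(p))
  }
  grid <- psd_welch(p, segment_length = segment_length,
                    segment_seconds = segment_seconds, window = window,
                    overlap = overlap, average_seconds = average_seconds)
  band_spl(grid, f_lo, f_hi)
}

grid_times <- function(grid) {
  if (inherits(grid$start_time, "POSIXct")) grid$start_time + grid$times
  else grid$start_time + grid$times
}
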