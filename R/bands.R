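# One-third-octave bands on the base-ten ladder: exact centre frequencies
# fc(n) = 10^(n/10) Hz, edges fc * 10^(+/- 1/20); successive lower edges are
# a factor 10^(1/10) apart (constant Q). Nominal labels follow the preferred
# numbers used on instrument front panels (..., 63, 80, 100, 125, ... Hz).

tol_preferred <- c(1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8)

#' One-third-octave band table
#'
#' Exact base-ten band definitions for the given band numbers: centre
#' `10^(n/10)` Hz, edges `centre * 10^(-1/20)` and `centre * 10^(1/20)`, and
#' the rounded preferred-number nominal label (band 18 is the 63 Hz band,
#' band 21 the 125 Hz band).
#'
#' @param bands Integer band numbers.
#' @return A tibble with columns `band`, `center`, `lower`, `upper`,
#'   `nominal`.
#' @export
#' @examples
#' tol_bands(c(18, 21))
tol_bands <- function(bands) {
  bands <- as.integer(bands)
  center <- 10^(bands / 10)
  tibble::tibble(
    band = bands,
    center = center,
    lower = center * 10^(-1 / 20),
    upper = center * 10^(1 / 20),
    nominal = tol_preferred[bands %% 10L + 1L] * 10^(bands %/% 10L)
  )
}

#' One-third-octave band levels from a PSD grid
#'
#' Integrates calibrated PSD power within each 1/3-octave band per time
#' step: `level = 10*log10(sum(P*df) / p_ref^2)` over the PSD bins whose
#' centre frequency falls inside the band edges (no bin splitting). Bands
#' whose upper edge exceeds the Nyquist frequency, or that contain no PSD
#' bin, are excluded.
#'
#' @param grid A `psd_grid` from [psd_welch()] or [spectrogram()].
#' @param bands Integer band numbers to attempt (default: every band
#'   resolvable by the grid).
#' @return A `band_series`: a long tibble with columns `time`, `band`,
#'   `center`, `nominal`, `lower`, `upper` and `level` (dB re p_ref), with
#'   the grid's reference pressure and start time as attributes.
#' @export
#' @examples
#' p <- synth_white_noise(60, duration = 20, sample_rate = 2000, seed = 1)
#' g <- psd_welch(p, segment_seconds = 2, average_seconds = 20)
#' third_octave_levels(g)
third_octave_levels <- function(grid, bands = NULL) {
  stopifnot(inherits(grid, "psd_grid"))
  nyq <- grid$sample_rate / 2
  df <- grid$sample_rate / grid$config$segment_length
  if (is.null(bands)) {
    n_max <- floor(10 * log10(nyq))
    bands <- seq.int(0L, n_max)
  }
  tbl <- tol_bands(bands)
  tbl <- tbl[tbl$upper <= nyq + 1e-9, , drop = FALSE]
  has_bin <- vapply(seq_len(nrow(tbl)), function(i) {
    any(grid$frequencies >= tbl$lower[i] & grid$frequencies <= tbl$upper[i] &
          grid$frequencies > 0)
  }, logical(1L))
  tbl <- tbl[has_bin, , drop = FALSE]
  if (nrow(tbl) == 0L) {
    abort("No complete 1/3-octave band within the grid's frequency range.")
  }
  times <- grid_times(grid)
  out <- purrr::map_dfr(seq_len(nrow(tbl)), function(i) {
    pw <- band_power(grid, max(tbl$lower[i], df / 2), tbl$upper[i])
    tibble::tibble(
      time = times,
      band = tbl$band[i],
      center = tbl$center[i],
      nominal = tbl$nominal[i],
      lower = tbl$lower[i],
      upper = tbl$upper[i],
      level = 10 * log10(pw / grid$p_ref^2)
    )
  })
  structure(
    dplyr::arrange(out, .data$time, .data$band),
    class = c("band_series", class(out)),
    p_ref = grid$p_ref,
    start_time = grid$start_time
  )
}
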