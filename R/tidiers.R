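#' Tidy a PSD grid into a long tibble
#'
#' @param x A `psd_grid`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `frequency`, `level`.
#' @export
tidy.psd_grid <- function(x, ...) {
  times <- grid_times(x)
  tibble::tibble(
    time = rep(times, each = length(x$frequencies)),
    frequency = rep(x$frequencies, times = length(times)),
    level = as.vector(x$levels)
  )
}

#' One-row summary of a PSD grid
#'
#' @param x A `psd_grid`.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, resolutions and configuration.
#' @export
glance.psd_grid <- function(x, ...) {
  tibble::tibble(
    n_frequencies = length(x$frequencies),
    n_times = length(x$times),
    delta_f = x$sample_rate / x$config$segment_length,
    nyquist = x$sample_rate / 2,
    window = x$config$window,
    segment_length = x$config$segment_length,
    overlap = x$config$overlap,
    average_seconds = x$config$average_seconds %||% NA_real_,
    p_ref = x$p_ref,
    clipped_fraction = x$clipped_fraction
  )
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.psd_grid <- function(x, ...) tidy(x, ...)

#' Export a PSD grid or band series as long-form CSV
#'
#' Writes `time, frequency, level` (PSD) or the band-series columns, one row
#' per cell, with fixed float formatting so repeated runs are bitwise
#' identical.
#'
#' @param x A `psd_grid`, `band_series`, `spd` or plain data frame.
#' @param path Output CSV path.
#' @param digits Significant digits for numeric formatting.
#' @return `path`, invisibly.
#' @export
write_levels_csv <- function(x, path, digits = 10) {
  if (inherits(x, "psd_grid")) x <- tidy(x)
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1L))
  x[num] <- lapply(x[num], function(col) signif(col, digits))
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
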