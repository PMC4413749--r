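#' Normalized audio segment
#'
#' An `audio_segment` holds dimensionless full-scale audio samples in
#' \[-1, 1\] together with sampling metadata. It is the common currency
#' between file reading ([read_wav()]), the simulated acquisition chain
#' ([simulate_recorder()]) and calibration ([apply_calibration()]).
#'
#' The clipped fraction is the proportion of samples whose magnitude is at or
#' above the saturation threshold (default 0.99 of full scale). Recorders and
#' limiters rarely park clipped samples exactly at 1.0, so a threshold just
#' below full scale catches rounded clips too.
#'
#' @param samples Numeric vector of normalized samples in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param start_time Recording start: a `POSIXct`, or an offset in seconds.
#' @param bit_depth One of 16, 24, 32 or `"float"`; the encoding the samples
#'   came from (or are destined for).
#' @param partial Logical; `TRUE` marks a short final segment from
#'   [stream_segments()].
#' @param clip_threshold Saturation threshold on `abs(samples)` used for
#'   `clipped_fraction`.
#'
#' @return An object of class `audio_segment`: a list with elements
#'   `samples`, `sample_rate`, `start_time`, `bit_depth`, `clipped_fraction`
#'   and `partial`.
#' @seealso [read_wav()], [apply_calibration()], [simulate_recorder()]
#' @export
#' @examples
#' seg <- audio_segment(sin(2 * pi * 100 * (0:999) / 8000) * 0.5, 8000)
#' seg$clipped_fraction # 0: peak well below full scale
audio_segment <- function(samples, sample_rate, start_time = 0,
                          bit_depth = "float", partial = FALSE,
                          clip_threshold = 0.99) {
  if (!is.numeric(samples)) abort("`samples` must be numeric.")
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  bit_depth <- check_bit_depth(bit_depth)
  if (any(abs(samples) > 1 + 1e-12, na.rm = TRUE)) {
    abort("`samples` must be normalized to [-1, 1].")
  }
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate = sample_rate,
      start_time = start_time,
      bit_depth = bit_depth,
      clipped_fraction = if (length(samples)) {
        mean(abs(samples) >= clip_threshold)
      } else 0,
      partial = isTRUE(partial)
    ),
    class = "audio_segment"
  )
}

check_bit_depth <- function(bit_depth) {
  if (identical(bit_depth, "float")) return("float")
  if (is_scalar_number(bit_depth) && bit_depth %in% c(16, 24, 32)) {
    return(as.integer(bit_depth))
  }
  abort("`bit_depth` must be one of 16, 24, 32 or \"float\".")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf(
    "<audio_segment> %d samples @ %g Hz (%.3f s), bit depth %s\n",
    length(x$samples), x$sample_rate, length(x$samples) / x$sample_rate,
    as.character(x$bit_depth)
  ))
  cat(sprintf(
    "  start: %s | clipped: %.4g%%%s\n",
    format(x$start_time), 100 * x$clipped_fraction,
    if (x$partial) " | partial" else ""
  ))
  invisible(x)
}

#' @export
length.audio_segment <- function(x) length(x$samples)
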