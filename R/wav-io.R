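# RIFF/WAVE reading and writing for PCM 16/24/32-bit integer and IEEE
# float-32 encodings. Integer codes are normalized by the positive full-scale
# code 2^(bits-1): the most negative code maps to exactly -1.0 and +1.0 is
# never reached by integer data (largest positive code is 2^(bits-1) - 1).

WAVE_FORMAT_PCM <- 1L
WAVE_FORMAT_IEEE_FLOAT <- 3L
WAVE_FORMAT_EXTENSIBLE <- 65534L

read_uint <- function(con, size) {
  v <- readBin(con, "integer", n = 1L, size = size, signed = size > 2,
               endian = "little")
  if (length(v) == 0L) abort("Unexpected end of file in WAV header.")
  if (v < 0) v <- v + 2^(8 * size) # sizes occasionally exceed int range
  v
}

# Parse the RIFF chunk list; returns fmt fields plus data-chunk location.
parse_wav_header <- function(con, path) {
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file (no RIFF tag).", path))
  }
  read_uint(con, 4L)
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file (no WAVE tag).", path))
  }
  info <- list(path = path)
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- read_uint(con, 4L)
    pos <- seek(con, NA)
    if (identical(id, "fmt ")) {
      fmt <- read_uint(con, 2L)
      info$n_channels <- read_uint(con, 2L)
      info$sample_rate <- read_uint(con, 4L)
      read_uint(con, 4L) # byte rate
      info$block_align <- read_uint(con, 2L)
      info$bits <- read_uint(con, 2L)
      if (fmt == WAVE_FORMAT_EXTENSIBLE && size >= 40L) {
        read_uint(con, 2L) # cbSize
        read_uint(con, 2L) # valid bits
        read_uint(con, 4L) # channel mask
        fmt <- read_uint(con, 2L) # first two bytes of the subformat GUID
      }
      info$format <- fmt
    } else if (identical(id, "data")) {
      info$data_offset <- pos
      info$data_size <- size
    }
    # chunk payloads are word-aligned
    seek(con, pos + size + (size %% 2L))
  }
  if (is.null(info$format)) abort(sprintf("'%s': no fmt chunk found.", path))
  if (is.null(info$data_offset)) {
    abort(sprintf("'%s': no data chunk found.", path))
  }
  if (!info$format %in% c(WAVE_FORMAT_PCM, WAVE_FORMAT_IEEE_FLOAT)) {
    abort(sprintf(
      "'%s': unsupported WAV encoding (format tag %d); only PCM (1) and IEEE float (3) are supported.",
      path, info$format
    ))
  }
  if (info$format == WAVE_FORMAT_PCM && !info$bits %in% c(16L, 24L, 32L)) {
    abort(sprintf(
      "'%s': unsupported PCM bit depth %d; only 16/24/32-bit integer and float-32 are supported.",
      path, info$bits
    ))
  }
  if (info$format == WAVE_FORMAT_IEEE_FLOAT && info$bits != 32L) {
    abort(sprintf("'%s': unsupported float bit depth %d.", path, info$bits))
  }
  info$bytes_per_sample <- info$bits %/% 8L
  info$n_frames <- info$data_size %/% info$block_align
  info$bit_depth <- if (info$format == WAVE_FORMAT_IEEE_FLOAT) "float" else info$bits
  info
}

#' Inspect a WAV file header
#'
#' @param path Path to a RIFF/WAVE file.
#' @return A one-row tibble: sample rate, channels, bit depth, frames,
#'   duration in seconds.
#' @export
wav_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  info <- parse_wav_header(con, path)
  tibble::tibble(
    path = path,
    sample_rate = info$sample_rate,
    n_channels = info$n_channels,
    bit_depth = as.character(info$bit_depth),
    n_frames = info$n_frames,
    duration = info$n_frames / info$sample_rate
  )
}

# Decode `n_frames` frames starting at 1-based frame `from`; extracts one
# channel and normalizes integer codes by 2^(bits-1).
read_frames <- function(con, info, from, n_frames, channel) {
  if (channel < 1L || channel > info$n_channels) {
    abort(sprintf(
      "Channel %d requested but '%s' has %d channel(s).",
      channel, info$path, info$n_channels
    ))
  }
  seek(con, info$data_offset + (from - 1) * info$block_align)
  n_values <- n_frames * info$n_channels
  bps <- info$bytes_per_sample
  if (identical(info$bit_depth, "float")) {
    x <- readBin(con, "numeric", n = n_values, size = 4L, endian = "little")
  } else if (info$bits == 24L) {
    raw <- readBin(con, "raw", n = n_values * 3L)
    m <- matrix(as.integer(raw), nrow = 3L)
    v <- m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else {
    v <- readBin(con, "integer", n = n_values, size = bps, signed = TRUE,
                 endian = "little")
    x <- v / 2^(info$bits - 1L)
  }
  if (info$n_channels > 1L) {
    x <- x[seq.int(channel, length(x), by = info$n_channels)]
  }
  x
}

#' Read a WAV file into a normalized audio segment
#'
#' Reads PCM 16/24/32-bit integer or IEEE float-32 RIFF/WAVE data and
#' normalizes integer codes to dimensionless full-scale units by dividing by
#' the positive full-scale code `2^(bits-1)`, so a 16-bit code of -32768 maps
#' to exactly -1.0 and +32767 to just under +1.0. Float data pass through
#' unscaled. Multi-channel files are reduced to the requested channel.
#'
#' @param path Path to the WAV file.
#' @param channel 1-based channel index to extract (default first channel).
#' @param start_time Recording start time attached to the result (`POSIXct`
#'   or offset seconds); not read from the file.
#' @inheritParams audio_segment
#' @return An [audio_segment()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".wav")
#' write_wav(sin(2 * pi * 440 * (0:7999) / 8000) * 0.5, f, 8000)
#' seg <- read_wav(f)
#' range(seg$samples)
read_wav <- function(path, channel = 1L, start_time = 0,
                     clip_threshold = 0.99) {
  con <- file(path, "rb")
  on.exit(close(con))
  info <- parse_wav_header(con, path)
  x <- read_frames(con, info, 1L, info$n_frames, channel)
  audio_segment(x, info$sample_rate, start_time = start_time,
                bit_depth = info$bit_depth, clip_threshold = clip_threshold)
}

#' Stream a WAV file as fixed-length segments
#'
#' Reads a (possibly very long) WAV file in contiguous, non-overlapping
#' segments of `segment_seconds` without ever holding the whole file in
#' memory. The final segment may be shorter and is marked `partial`; segment
#' start times advance by exactly the segment length.
#'
#' @inheritParams read_wav
#' @param segment_seconds Segment length in seconds (> 0).
#' @return A list of [audio_segment()]s covering the file; concatenating
#'   their samples reproduces `read_wav(path)$samples` exactly.
#' @export
stream_segments <- function(path, segment_seconds, channel = 1L,
                            start_time = 0, clip_threshold = 0.99) {
  stopifnot_scalar(segment_seconds, "segment_seconds", positive = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  info <- parse_wav_header(con, path)
  frames_per_seg <- max(1L, as.integer(round(segment_seconds * info$sample_rate)))
  starts <- seq.int(1L, max(info$n_frames, 1L), by = frames_per_seg)
  purrr::map(starts, function(from) {
    n <- min(frames_per_seg, info$n_frames - from + 1L)
    x <- read_frames(con, info, from, n, channel)
    t0 <- (from - 1L) / info$sample_rate
    audio_segment(
      x, info$sample_rate,
      start_time = if (inherits(start_time, "POSIXct")) start_time + t0 else start_time + t0,
      bit_depth = info$bit_depth,
      partial = n < frames_per_seg,
      clip_threshold = clip_threshold
    )
  })
}

# Quantize normalized samples to signed integer codes of the given bit depth;
# codes are clamped to [-2^(bits-1), 2^(bits-1) - 1].
quantize_codes <- function(x, bits) {
  full <- 2^(bits - 1L)
  pmin(pmax(round(x * full), -full), full - 1)
}

#' Write samples to a WAV file
#'
#' Writes normalized samples (or an [audio_segment()]) as a mono RIFF/WAVE
#' file. Integer encodings quantize by rounding `samples * 2^(bits-1)` and
#' clamp to the representable code range; float-32 writes samples verbatim.
#'
#' @param x Numeric vector in \[-1, 1\] or an [audio_segment()].
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz (taken from `x` if an
#'   `audio_segment`).
#' @param bit_depth 16, 24, 32 or `"float"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = NULL, bit_depth = 16) {
  if (inherits(x, "audio_segment")) {
    sample_rate <- sample_rate %||% x$sample_rate
    x <- x$samples
  }
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  bit_depth <- check_bit_depth(bit_depth)
  is_float <- identical(bit_depth, "float")
  bits <- if (is_float) 32L else bit_depth
  bps <- bits %/% 8L
  n <- length(x)
  data_size <- n * bps
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(if (is_float) WAVE_FORMAT_IEEE_FLOAT else WAVE_FORMAT_PCM, con,
           size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * bps), con, size = 4L, endian = "little")
  writeBin(as.integer(bps), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (is_float) {
    writeBin(as.numeric(x), con, size = 4L, endian = "little")
  } else if (bits == 24L) {
    v <- quantize_codes(x, 24L)
    v <- ifelse(v < 0, v + 2^24, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  } else {
    writeBin(as.integer(quantize_codes(x, bits)), con, size = bps,
             endian = "little")
  }
  invisible(path)
}
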