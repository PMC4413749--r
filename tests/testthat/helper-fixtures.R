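# shared fixtures: a realistic hydrophone chain and small signal builders

hydro_spec <- function(...) {
  cal_spec("water", sensitivity = -165, gain = 20, adc_peak_voltage = 1, ...)
} # S = -145 dB re FS/uPa: full scale = 10^(145/20) ~ 1.78e7 uPa (~178 dB pk)

# hand-built mono 16-bit WAV from raw integer codes, independent of
# write_wav(), for oracle-grade decoding checks
write_pcm16_by_hand <- function(codes, path, sample_rate = 8000,
                                n_channels = 1L, format_tag = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(codes) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(as.integer(format_tag), con, size = 2L, endian = "little")
  writeBin(as.integer(n_channels), con, size = 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L * n_channels), con, size = 4L,
           endian = "little")
  writeBin(2L * as.integer(n_channels), con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(as.integer(codes), con, size = 2L, endian = "little")
  invisible(path)
}

# a noise-floor-limited recording: a pink-noise habitat whose level varies
# in 8 dB (sd) steps every 5 s, recorded by an instrument with a flat
# self-noise floor at 38 dB re 1 uPa^2/Hz; at high frequency the habitat
# falls below the floor and the level distribution collapses onto it
floor_limited_grid <- function(seed, duration = 300) {
  fs <- 4000
  spec <- cal_spec("water", end_to_end = -105)
  base <- synth_pink_noise(50, duration = duration, sample_rate = fs,
                           seed = seed, f_ref = 10)
  n_block <- duration / 5
  gains <- withr::with_seed(seed + 1,
                            rep(10^(rnorm(n_block, 0, 8) / 20),
                                each = 5 * fs))
  habitat <- pressure_series(base$pressure * gains, fs)
  seg <- simulate_recorder(habitat, spec, bit_depth = "float",
                           self_noise_density = 38, seed = seed + 2)
  psd_welch(apply_calibration(seg, spec), segment_seconds = 0.5,
            overlap = 0, average_seconds = 5)
}

# brute-force band-pass by zeroing FFT bins outside [f_lo, f_hi], then RMS
# level: an independent time-domain route to band SPL
bandpass_rms_level <- function(p, f_lo, f_hi) {
  x <- p$pressure
  n <- length(x)
  sp <- stats::fft(x)
  freqs <- (seq_len(n) - 1L) * p$sample_rate / n
  freqs <- ifelse(freqs > p$sample_rate / 2, p$sample_rate - freqs, freqs)
  sp[freqs < f_lo | freqs > f_hi] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  10 * log10(mean(y^2) / p$p_ref^2)
}
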