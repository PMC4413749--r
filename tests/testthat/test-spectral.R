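test_that("window constants: rectangular is 1 bin wide; periodic Hann has gain 0.5, 1.5 bins", {
  expect_equal(window_coefficients("rectangular", 333)$enbw_bins, 1.0)
  expect_equal(window_coefficients("rectangular", 333)$coherent_gain, 1.0)
  # periodic Hann: sum(w) = N/2 and sum(w^2) = 3N/8 exactly at any N
  for (n in c(64, 1024)) {
    wc <- window_coefficients("hann", n)
    expect_equal(wc$coherent_gain, 0.5, tolerance = 1e-12)
    expect_equal(wc$enbw_bins, 1.5, tolerance = 1e-12)
  }
  expect_gt(window_coefficients("hamming", 512)$enbw_bins, 1.3)
  expect_error(window_coefficients("blackman", 64), "Unknown window")
})

test_that("Parseval: summed single-sided PSD power x bin width equals the mean square", {
  fs <- 2000
  p <- synth_white_noise(60, duration = 4, sample_rate = fs, seed = 11)
  g <- psd_welch(p, segment_length = 500, window = "rectangular",
                 overlap = 0, average_seconds = 4)
  df <- fs / 500
  total <- sum(10^(g$levels[, 1] / 10)) * df
  ms <- mean(p$pressure^2)
  expect_lt(abs(total - ms) / ms, 1e-6)
})

test_that("a pure tone at a bin centre recovers its power and level", {
  fs <- 8000
  a <- sqrt(2) * 10^(100 / 20) # SPL 100 dB re 1 uPa
  p <- synth_tone(1000, spl = 100, duration = 2, sample_rate = fs)
  g <- psd_welch(p, segment_length = fs, overlap = 0, average_seconds = 2)
  df <- fs / fs
  total <- sum(10^(g$levels[, 1] / 10)) * df
  expect_equal(total, a^2 / 2, tolerance = 1e-3)
  expect_equal(broadband_spl(p, segment_seconds = 1)$spl[1L], 100,
               tolerance = 0.01)
})

test_that("white noise yields a flat PSD at the closed-form density", {
  fs <- 2000
  density <- 60 # dB re 1 uPa^2/Hz
  p <- synth_white_noise(density, duration = 100, sample_rate = fs,
                         seed = 5)
  g <- psd_welch(p, segment_seconds = 1, overlap = 0, average_seconds = 100)
  # power-domain mean over bins (drop DC) vs sigma^2/(fs/2)
  mean_level <- 10 * log10(mean(10^(g$levels[-1, 1] / 10)))
  expect_equal(mean_level, density, tolerance = 0.2)
})

test_that("Welch averaging groups segments as configured", {
  fs <- 1000
  p <- synth_white_noise(50, duration = 60, sample_rate = fs, seed = 2)
  g <- psd_welch(p, segment_seconds = 1, overlap = 0, average_seconds = 60)
  expect_equal(ncol(g$levels), 1L)
  expect_equal(g$n_segments, 60L)
  g2 <- psd_welch(p, segment_seconds = 1, overlap = 0, average_seconds = 10)
  expect_equal(ncol(g2$levels), 6L)
  expect_equal(g2$n_segments, rep(10L, 6L))
  expect_error(psd_welch(p, segment_seconds = 1, average_seconds = 0.5),
               "at least one segment")
  expect_error(
    psd_welch(synth_tone(10, 60, 0.1, fs), segment_seconds = 1),
    "samples"
  )
})

test_that("estimator variance shrinks like 1/K with K averaged segments", {
  fs <- 2000
  n_rep <- 120
  bin <- 26L # fixed frequency bin
  var_k <- vapply(c(1, 4, 16), function(k) {
    est <- vapply(seq_len(n_rep), function(r) {
      p <- synth_white_noise(60, duration = k * 256 / fs, sample_rate = fs,
                             seed = 1000 * k + r)
      g <- psd_welch(p, segment_length = 256, window = "rectangular",
                     overlap = 0, average_seconds = k * 256 / fs)
      10^(g$levels[bin, 1] / 10)
    }, numeric(1L))
    stats::var(est)
  }, numeric(1L))
  expect_gt(var_k[1L] / var_k[2L], 2.3)
  expect_lt(var_k[1L] / var_k[2L], 7)
  expect_gt(var_k[2L] / var_k[3L], 2.3)
  expect_lt(var_k[2L] / var_k[3L], 7)
})

test_that("spectrogram is the unaveraged estimator and honours overlap", {
  fs <- 96000
  p <- synth_white_noise(60, duration = 1, sample_rate = fs, seed = 9)
  g <- spectrogram(p, segment_seconds = 0.05, overlap = 0.99)
  # hop = 0.0005 s -> floor((L - N)/hop) + 1 columns
  expect_equal(length(g$times), floor((fs - 4800) / 48) + 1) # 1901

  p2 <- synth_white_noise(55, duration = 20, sample_rate = 2000, seed = 10)
  sg <- spectrogram(p2, segment_seconds = 1, overlap = 0.5)
  we <- psd_welch(p2, segment_seconds = 1, overlap = 0.5,
                  average_seconds = 20)
  col_mean <- 10 * log10(rowMeans(10^(sg$levels / 10)))
  expect_equal(col_mean, we$levels[, 1], tolerance = 1e-9)
})

test_that("a rising chirp produces a monotonically rising spectrogram ridge", {
  fs <- 4000
  t <- (0:(2 * fs - 1)) / fs
  # linear sweep 100 -> 900 Hz over 2 s
  x <- sin(2 * pi * (100 * t + (800 / (2 * 2)) * t^2))
  p <- pressure_series(x, fs)
  g <- spectrogram(p, segment_length = 256, overlap = 0.5)
  ridge <- g$frequencies[apply(g$levels, 2L, which.max)]
  expect_true(all(diff(ridge) >= 0))
})

test_that("band-limited SPL matches an independent band-pass-then-RMS route", {
  fs <- 4000
  p <- synth_pink_noise(70, duration = 30, sample_rate = fs, seed = 13)
  got <- broadband_spl(p, f_lo = 200, f_hi = 1000, segment_seconds = 1,
                       overlap = 0, average_seconds = 30)$spl[1L]
  oracle <- bandpass_rms_level(p, 200, 1000)
  expect_equal(got, oracle, tolerance = 0.5)
})

test_that("full-band SPL equals the time-domain RMS level", {
  p <- synth_white_noise(65, duration = 4, sample_rate = 2000, seed = 21)
  got <- broadband_spl(p, segment_length = 500, window = "rectangular",
                       overlap = 0, average_seconds = 4)$spl[1L]
  expect_equal(got, spl_rms(p), tolerance = 1e-6)
  expect_error(band_spl(psd_welch(p, segment_seconds = 1), 500, 400),
               "f_lo")
})
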