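test_that("symmetric pulses have SPL_pp exactly 6.02 dB above SPL_0p", {
  p <- synth_tone(200, spl = 150, duration = 0.1, sample_rate = 8000)
  pk <- peak_levels(p)
  expect_equal(pk$spl_peak_to_peak - pk$spl_zero_to_peak, 20 * log10(2),
               tolerance = 1e-6)
})

test_that("a single positive spike has equal zero-to-peak and peak-to-peak levels", {
  x <- numeric(1000)
  x[500] <- 2500 # uPa
  p <- pressure_series(x, 8000)
  pk <- peak_levels(p)
  expect_equal(pk$spl_zero_to_peak, 20 * log10(2500))
  expect_equal(pk$spl_peak_to_peak, pk$spl_zero_to_peak)
  expect_error(peak_levels(pressure_series(numeric(100), 8000)),
               "all-zero")
})

test_that("peak levels of a decaying sinusoid match a direct-max oracle", {
  p <- synth_impulse(160, decay_s = 0.02, carrier_hz = 500, duration = 0.5,
                     sample_rate = 48000)
  pk <- peak_levels(p)
  expect_equal(pk$spl_zero_to_peak, 20 * log10(max(abs(p$pressure))))
  expect_equal(pk$spl_zero_to_peak, 160, tolerance = 1e-9)
  expect_equal(pk$spl_peak_to_peak,
               20 * log10(max(p$pressure) - min(p$pressure)))
  # peak metrics never differ by more than 20*log10(2)
  expect_lte(pk$spl_peak_to_peak, pk$spl_zero_to_peak + 20 * log10(2) + 1e-9)
  expect_gte(pk$spl_peak_to_peak, pk$spl_zero_to_peak)
})

test_that("a rectangular pulse has tau90 = 0.9 T and ~90% envelope energy", {
  fs <- 10000
  T_pulse <- 0.2
  x <- numeric(fs)
  x[1:(T_pulse * fs)] <- 1000
  p <- pressure_series(x, fs)
  env <- energy_envelope(p)
  expect_equal(env$tau90, 0.9 * T_pulse, tolerance = 2 / fs)
  expect_equal(env$energy_fraction, 0.9, tolerance = 2 / (T_pulse * fs))
  expect_equal(env$t95 - env$t5, env$tau90)
})

test_that("envelope thresholds agree with a brute-force cumulative sum", {
  p <- synth_impulse(150, decay_s = 0.01, carrier_hz = 300, duration = 0.3,
                     sample_rate = 20000)
  env <- energy_envelope(p)
  e <- cumsum(p$pressure^2) / p$sample_rate
  t5_oracle <- (which(e >= 0.05 * e[length(e)])[1L] - 1) / p$sample_rate
  t95_oracle <- (which(e >= 0.95 * e[length(e)])[1L] - 1) / p$sample_rate
  expect_equal(env$t5, t5_oracle)
  expect_equal(env$t95, t95_oracle)
  # front-loaded decay: t5 early, duration well under 90% of the window
  expect_lt(env$t5, 0.15)
  expect_lt(env$tau90, 0.9 * duration(p))
  expect_error(energy_envelope(pressure_series(numeric(100), 1000)),
               "zero total energy")
  expect_error(energy_envelope(p, lo = 0.9, hi = 0.1), "lo < hi")
})

test_that("envelope bounds are monotone in (lo, hi) and bound the envelope SEL", {
  p <- synth_impulse(150, decay_s = 0.02, carrier_hz = 300, duration = 0.4,
                     sample_rate = 20000)
  e90 <- energy_envelope(p, lo = 0.05, hi = 0.95)
  e50 <- energy_envelope(p, lo = 0.25, hi = 0.75)
  e98 <- energy_envelope(p, lo = 0.01, hi = 0.99)
  expect_lte(e50$tau90, e90$tau90)
  expect_lte(e90$tau90, e98$tau90)
  full <- pulse_sel(p)
  expect_lte(e90$sel_in_envelope, full)
  expect_lte(full - e90$sel_in_envelope, 10 * log10(1 / 0.9) + 1e-9)
})

test_that("tau90 is scale-invariant while dB metrics shift by 20*log10(k)", {
  p <- synth_impulse(140, decay_s = 0.015, carrier_hz = 400, duration = 0.3,
                     sample_rate = 20000)
  k <- 3.7
  p2 <- pressure_series(p$pressure * k, p$sample_rate, p$start_time,
                        p$p_ref)
  env1 <- energy_envelope(p)
  env2 <- energy_envelope(p2)
  expect_equal(env2$tau90, env1$tau90)
  shift <- 20 * log10(k)
  expect_equal(peak_levels(p2)$spl_zero_to_peak,
               peak_levels(p)$spl_zero_to_peak + shift)
  expect_equal(pulse_sel(p2), pulse_sel(p) + shift)
  expect_equal(env2$sel_in_envelope, env1$sel_in_envelope + shift)
})

test_that("pulse SEL equals the general SEL and is additive over identical pulses", {
  fs <- 20000
  one <- synth_impulse(150, decay_s = 0.01, carrier_hz = 300,
                       duration = 0.5, sample_rate = fs)
  two <- synth_impulse(150, decay_s = 0.01, carrier_hz = 300,
                       duration = 1, sample_rate = fs, interval_s = 0.5)
  expect_equal(pulse_sel(one, c(0, 0.5)), sel(one, 0, 0.5))
  expect_equal(pulse_sel(two, c(0, 1)), pulse_sel(one, c(0, 0.5)) +
                 10 * log10(2), tolerance = 1e-6)
  # sine burst closed form: 10*log10((A^2/2) * T)
  a <- 5000
  t_burst <- 0.25
  burst <- pressure_series(
    c(a * sin(2 * pi * 400 * seq(0, t_burst - 1 / fs, by = 1 / fs)),
      numeric(fs / 4)), fs
  )
  expect_equal(pulse_sel(burst, c(0, t_burst)),
               10 * log10(a^2 / 2 * t_burst), tolerance = 1e-3)
})

test_that("SNR gate: valid at >= 10 dB, invalid below, ~0 dB for pure noise", {
  fs <- 8000
  set.seed(71)
  noise <- rnorm(2 * fs, sd = 100)
  target_rms <- 100 * 10^(20 / 20) # 20 dB above the noise RMS
  pulse <- sqrt(2) * target_rms * sin(2 * pi * 500 * (0:(fs / 2 - 1)) / fs)
  p <- pressure_series(c(noise[1:fs], pulse, noise[(fs + 1):(1.5 * fs)]), fs)
  qc <- snr_check(p, pulse_window = c(1, 1.5), noise_window = c(0, 1))
  expect_equal(qc$snr, 20, tolerance = 0.5)
  expect_true(qc$valid)

  # boundary behaviour, exactly at and just below threshold
  flat <- pressure_series(rep(c(1, -1), 1000), 1000)
  expect_true(snr_check(flat, c(1, 2), c(0, 1), threshold = 0)$valid)
  q1 <- snr_check(p, c(1, 1.5), c(0, 1), threshold = qc$snr)
  expect_true(q1$valid) # snr == threshold is valid
  q2 <- snr_check(p, c(1, 1.5), c(0, 1), threshold = qc$snr + 0.1)
  expect_false(q2$valid)

  # no pulse present: snr ~ 0, invalid
  q0 <- snr_check(p, c(0, 0.5), c(0.5, 1))
  expect_lt(abs(q0$snr), 1)
  expect_false(q0$valid)

  expect_error(snr_check(p, c(0.5, 1.5), c(0, 1)), "disjoint")
})

test_that("pulse_metrics bundles all fields and warns on non-flat system response", {
  p <- synth_mixture(
    synth_impulse(150, decay_s = 0.005, carrier_hz = 400, duration = 2,
                  sample_rate = 8000),
    synth_white_noise(20, duration = 2, sample_rate = 8000, seed = 72)
  )
  pm <- pulse_metrics(p, pulse_window = c(0, 0.2),
                      noise_window = c(1, 2))
  expect_named(pm, c("t_start", "t_end", "spl_zero_to_peak",
                     "spl_peak_to_peak", "sel_pulse", "t5", "t95", "tau90",
                     "sel_in_envelope", "snr", "valid"))
  expect_true(pm$valid)
  expect_lte(pm$sel_in_envelope, pm$sel_pulse)

  wobbly <- cal_spec("water", end_to_end = -140,
                     frequency_response = data.frame(
                       frequency = c(200, 400, 800),
                       correction_db = c(-20, 0, -20)
                     ))
  expect_warning(
    pulse_metrics(p, c(0, 0.2), c(1, 2), cal = wobbly),
    "varies"
  )
  flat <- cal_spec("water", end_to_end = -140,
                   frequency_response = data.frame(
                     frequency = c(100, 800), correction_db = c(0, -0.5)
                   ))
  expect_no_warning(pulse_metrics(p, c(0, 0.2), c(1, 2), cal = flat))
})
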