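# Synthetic-signal generators with machine-readable ground truth, plus a
# forward simulation of the acquisition chain (sensitivity, gain, additive
# self-noise, clipping, quantization). Together they make every analysis in
# the package testable without field recordings.

truth <- function(p) attr(p, "truth")

set_truth <- function(p, ...) {
  attr(p, "truth") <- list(...)
  p
}

#' Pure tone at an exact sound pressure level
#'
#' A sinusoid whose amplitude is set analytically from the requested level:
#' `A = sqrt(2) * p_ref * 10^(spl/20)`, so the broadband RMS level equals
#' `spl` exactly.
#'
#' @param frequency Tone frequency in Hz.
#' @param spl Target RMS level in dB re `p_ref`.
#' @param duration Length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param p_ref Reference pressure in uPa (1 underwater, 20 in air).
#' @param phase Initial phase in radians.
#' @param start_time `POSIXct` or offset seconds.
#' @return A [pressure_series()] with a `truth` attribute recording the
#'   requested ground-truth values.
#' @export
#' @examples
#' p <- synth_tone(1000, spl = 100, duration = 1, sample_rate = 8000)
#' spl_rms(p) # 100
synth_tone <- function(frequency, spl, duration, sample_rate, p_ref = 1,
                       phase = 0, start_time = 0) {
  stopifnot_scalar(frequency, "frequency", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  a <- sqrt(2) * p_ref * 10^(spl / 20)
  t <- seq.int(0L, round(duration * sample_rate) - 1L) / sample_rate
  p <- pressure_series(a * sin(2 * pi * frequency * t + phase),
                       sample_rate, start_time, p_ref)
  set_truth(p, kind = "tone", frequency = frequency, spl = spl,
            amplitude = a)
}

#' Gaussian white noise at an exact power spectral density
#'
#' White noise whose flat PSD equals `density_db` (dB re p_ref^2/Hz) in
#' expectation: variance `10^(density_db/10) * p_ref^2 * (sample_rate/2)`,
#' the density times the single-sided bandwidth.
#'
#' @param density_db Target PSD level in dB re p_ref^2/Hz.
#' @inheritParams synth_tone
#' @param seed Integer seed for reproducibility (`NULL` uses the current RNG
#'   state).
#' @return A [pressure_series()] with ground truth in `attr(, "truth")`.
#' @export
synth_white_noise <- function(density_db, duration, sample_rate, p_ref = 1,
                              start_time = 0, seed = NULL) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  n <- round(duration * sample_rate)
  sigma <- sqrt(10^(density_db / 10) * p_ref^2 * sample_rate / 2)
  x <- with_seed(seed, rnorm(n, sd = sigma))
  p <- pressure_series(x, sample_rate, start_time, p_ref)
  set_truth(p, kind = "white_noise", density_db = density_db,
            spl = 10 * log10(sigma^2 / p_ref^2), sigma = sigma, seed = seed)
}

#' Pink (1/f) noise
#'
#' White noise shaped in the frequency domain to a power density falling at
#' 3 dB per octave (amplitude proportional to `f^-0.5`). Because a 1/f
#' density has no single flat level, the target `density_db` is anchored at
#' a reference frequency (`f_ref`, default 100 Hz): the expected PSD at
#' frequency f is `density_db - 10*log10(f/f_ref)`.
#'
#' @param density_db PSD level at `f_ref`, dB re p_ref^2/Hz.
#' @param f_ref Anchor frequency in Hz.
#' @inheritParams synth_white_noise
#' @return A [pressure_series()].
#' @export
synth_pink_noise <- function(density_db, duration, sample_rate, p_ref = 1,
                             f_ref = 100, start_time = 0, seed = NULL) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  n <- round(duration * sample_rate)
  w <- with_seed(seed, rnorm(n))
  sp <- fft(w)
  freqs <- c(seq.int(0L, n %/% 2L), -rev(seq_len((n - 1L) %/% 2L))) *
    sample_rate / n
  shape <- ifelse(freqs == 0, 0, sqrt(f_ref / abs(freqs)))
  x <- Re(fft(sp * shape, inverse = TRUE)) / n
  # the white source has unit density 2/fs; rescale to the target at f_ref
  target_density <- 10^(density_db / 10) * p_ref^2
  x <- x * sqrt(target_density / (2 / sample_rate))
  p <- pressure_series(x, sample_rate, start_time, p_ref)
  set_truth(p, kind = "pink_noise", density_db = density_db, f_ref = f_ref,
            seed = seed)
}

#' Impulse train of decaying sinusoids at an exact peak level
#'
#' Airgun-like pulses: a carrier sinusoid under an exponential decay,
#' rescaled so the zero-to-peak pressure equals `peak_db` exactly. With
#' `interval_s` set, identical pulses repeat for the whole duration.
#'
#' @param peak_db Target zero-to-peak level in dB re `p_ref`.
#' @param decay_s Exponential decay time constant in seconds.
#' @param carrier_hz Carrier frequency in Hz.
#' @param interval_s Inter-pulse interval in seconds (`NULL` for a single
#'   pulse at `t = 0`).
#' @inheritParams synth_tone
#' @return A [pressure_series()].
#' @export
synth_impulse <- function(peak_db, decay_s, carrier_hz, duration,
                          sample_rate, p_ref = 1, interval_s = NULL,
                          start_time = 0) {
  stopifnot_scalar(decay_s, "decay_s", positive = TRUE)
  n <- round(duration * sample_rate)
  t <- seq.int(0L, n - 1L) / sample_rate
  pulse_t <- if (is.null(interval_s)) t else t %% interval_s
  x <- exp(-pulse_t / decay_s) * sin(2 * pi * carrier_hz * pulse_t)
  peak <- p_ref * 10^(peak_db / 20)
  x <- x * peak / max(abs(x))
  p <- pressure_series(x, sample_rate, start_time, p_ref)
  set_truth(p, kind = "impulse", peak_db = peak_db, decay_s = decay_s,
            carrier_hz = carrier_hz, interval_s = interval_s)
}

#' Diel-cycle noise: a day/night step in level
#'
#' Gaussian noise whose broadband level steps up by `day_offset_db` during
#' daytime hours — a minimal emulation of the diel pattern seen in
#' terrestrial habitats, for testing hour-of-day aggregation.
#'
#' @param baseline_spl Night-time broadband RMS level, dB re `p_ref`.
#' @param day_offset_db Additional level during day hours, dB.
#' @param day_hours `c(first, last)` local hours of the raised period;
#'   hours h with `first <= h < last` are "day". Default `c(6, 18)`.
#' @inheritParams synth_white_noise
#' @param start_time `POSIXct` recording start (needed for meaningful
#'   hour-of-day grouping) or offset seconds (hours then count from 0).
#' @return A [pressure_series()].
#' @export
synth_diel_cycle <- function(baseline_spl, day_offset_db, duration,
                             sample_rate, day_hours = c(6, 18), p_ref = 1,
                             start_time = 0, seed = NULL) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  n <- round(duration * sample_rate)
  t <- seq.int(0L, n - 1L) / sample_rate
  start_hour <- if (inherits(start_time, "POSIXct")) {
    lubridate::hour(start_time) + lubridate::minute(start_time) / 60 +
      lubridate::second(start_time) / 3600
  } else 0
  hour_of_day <- (start_hour + t / 3600) %% 24
  is_day <- hour_of_day >= day_hours[1L] & hour_of_day < day_hours[2L]
  level <- baseline_spl + day_offset_db * is_day
  sigma <- p_ref * 10^(level / 20)
  x <- with_seed(seed, rnorm(n) * sigma)
  p <- pressure_series(x, sample_rate, start_time, p_ref)
  set_truth(p, kind = "diel_cycle", baseline_spl = baseline_spl,
            day_offset_db = day_offset_db, day_hours = day_hours,
            seed = seed)
}

#' Sum of synthetic components
#'
#' Adds pressure series sample by sample (they must share sampling rate and
#' length) — e.g. a tone over a noise floor.
#'
#' @param ... [pressure_series()] objects.
#' @return A [pressure_series()] with the component truths attached.
#' @export
synth_mixture <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "pressure_series")) {
    parts <- parts[[1L]]
  }
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1L), "pressure_series")))
  fs <- unique(vapply(parts, function(p) p$sample_rate, numeric(1L)))
  ns <- unique(vapply(parts, length, integer(1L)))
  if (length(fs) != 1L || length(ns) != 1L) {
    abort("Mixture components must share sample rate and length.")
  }
  x <- Reduce(`+`, lapply(parts, function(p) p$pressure))
  p <- pressure_series(x, fs, parts[[1L]]$start_time, parts[[1L]]$p_ref)
  set_truth(p, kind = "mixture", components = lapply(parts, truth))
}

#' Generate a synthetic pressure series from a declarative spec
#'
#' Dispatcher over the `synth_*` generators: `kind` selects the generator
#' and the remaining list elements are passed as arguments. Identical spec
#' (including `seed`) gives bit-identical output.
#'
#' @param spec A list with elements `kind` (one of `"tone"`,
#'   `"white_noise"`, `"pink_noise"`, `"impulse"`, `"diel_cycle"`,
#'   `"mixture"`) plus the generator's arguments; for `"mixture"`, a
#'   `components` list of sub-specs.
#' @return A [pressure_series()].
#' @export
#' @examples
#' p <- generate(list(kind = "tone", frequency = 250, spl = 90,
#'                    duration = 1, sample_rate = 4000))
generate <- function(spec) {
  if (!is.list(spec) || is.null(spec$kind)) {
    abort("`spec` must be a list with a `kind` element.")
  }
  kind <- spec$kind
  args <- spec[setdiff(names(spec), "kind")]
  switch(kind,
    tone = do.call(synth_tone, args),
    white_noise = do.call(synth_white_noise, args),
    pink_noise = do.call(synth_pink_noise, args),
    impulse = do.call(synth_impulse, args),
    diel_cycle = do.call(synth_diel_cycle, args),
    mixture = synth_mixture(lapply(args$components, generate)),
    abort(sprintf("Unknown synthetic signal kind '%s'.", kind))
  )
}

#' Simulate the acquisition chain of a PAM recorder
#'
#' Forward model of the recording system: scales pressure by the combined
#' sensitivity into dimensionless full-scale units, optionally adds flat
#' Gaussian system self-noise (specified as an equivalent pressure density),
#' clips at full scale, and quantizes to the requested bit depth. The
#' resulting [audio_segment()] is what [read_wav()] would return for that
#' recorder, so `simulate_recorder()` followed by [apply_calibration()] with
#' the same spec is an end-to-end round trip.
#'
#' @param p A [pressure_series()] (the true sound field).
#' @param spec A [cal_spec()] for the simulated instrument.
#' @param bit_depth 16, 24, 32 or `"float"`.
#' @param self_noise_density Optional self-noise level as an equivalent
#'   pressure PSD, dB re p_ref^2/Hz (flat); `NULL` for a noiseless system.
#' @param seed Seed for the self-noise.
#' @param clip_threshold Saturation threshold for the clipped fraction.
#' @return An [audio_segment()].
#' @export
#' @examples
#' spec <- cal_spec("water", end_to_end = -40)
#' p <- synth_tone(500, spl = 30, duration = 1, sample_rate = 4000)
#' seg <- simulate_recorder(p, spec)
#' spl_rms(apply_calibration(seg, spec)) # ~30 dB
simulate_recorder <- function(p, spec, bit_depth = 16,
                              self_noise_density = NULL, seed = NULL,
                              clip_threshold = 0.99) {
  stopifnot(inherits(p, "pressure_series"), inherits(spec, "cal_spec"))
  bit_depth <- check_bit_depth(bit_depth)
  s <- combined_sensitivity(spec)
  pr <- p$pressure
  if (!is.null(self_noise_density)) {
    sigma <- sqrt(10^(self_noise_density / 10) * spec$p_ref^2 *
                    p$sample_rate / 2)
    pr <- pr + with_seed(seed, rnorm(length(pr), sd = sigma))
  }
  x <- pr * 10^(s / 20)
  x <- pmin(pmax(x, -1), 1)
  if (!identical(bit_depth, "float")) {
    bits <- bit_depth
    x <- quantize_codes(x, bits) / 2^(bits - 1L)
  }
  audio_segment(x, p$sample_rate, start_time = p$start_time,
                bit_depth = bit_depth, clip_threshold = clip_threshold)
}
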