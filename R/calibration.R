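#' Calibration specification for a PAM acquisition chain
#'
#' Describes the signal path of a passive acoustic monitoring system —
#' transducer, pre-amplifier, analogue-to-digital converter — so that
#' dimensionless audio samples can be converted back to absolute sound
#' pressure. Either the three chain components are given, or a single
#' end-to-end sensitivity measured by injecting a known reference signal
#' (e.g. a pistonphone tone) at the transducer.
#'
#' Sign convention: `sensitivity` (M) is the transducer sensitivity in dB re
#' 1 V/uPa and is strongly negative for real instruments (a hydrophone
#' producing 10 uV per uPa has M = -100 dB re 1 V/uPa). Gain (G, dB) is
#' positive for amplification. The combined system sensitivity is
#' `S = M + G - 20*log10(adc_peak_voltage)` in dB re full-scale per uPa; a
#' full-scale sample then corresponds to a pressure of `10^(-S/20)` uPa.
#'
#' @param domain `"water"` or `"air"`; selects the decibel reference pressure
#'   (1 uPa underwater, 20 uPa in air). Pressures are always in uPa in both
#'   domains; only the reference used at dB conversion differs.
#' @param sensitivity Transducer sensitivity M in dB re 1 V/uPa.
#' @param gain Pre-amplifier gain G in dB.
#' @param adc_peak_voltage Zero-to-peak ADC input voltage (volts) mapping to
#'   digital full scale; must be > 0.
#' @param end_to_end End-to-end system sensitivity S in dB re full-scale per
#'   uPa; overrides the three component fields (supply either this or all
#'   three components, not both).
#' @param frequency_response Optional data frame with columns `frequency`
#'   (Hz, strictly increasing) and `correction_db` (relative response, dB)
#'   for frequency-dependent corrections; see
#'   [apply_frequency_response()].
#' @return An object of class `cal_spec`.
#' @export
#' @examples
#' # hydrophone at -165 dB re 1 V/uPa, 20 dB gain, 1 V peak ADC
#' spec <- cal_spec("water", sensitivity = -165, gain = 20, adc_peak_voltage = 1)
#' combined_sensitivity(spec) # -145 dB re full-scale per uPa
cal_spec <- function(domain = c("water", "air"), sensitivity = NULL,
                     gain = NULL, adc_peak_voltage = NULL,
                     end_to_end = NULL, frequency_response = NULL) {
  domain <- match.arg(domain)
  components <- c(
    !is.null(sensitivity), !is.null(gain), !is.null(adc_peak_voltage)
  )
  if (is.null(end_to_end)) {
    if (!all(components)) {
      abort(paste(
        "Provide either `end_to_end` or all three of `sensitivity`,",
        "`gain` and `adc_peak_voltage`."
      ))
    }
    stopifnot_scalar(sensitivity, "sensitivity")
    stopifnot_scalar(gain, "gain")
    stopifnot_scalar(adc_peak_voltage, "adc_peak_voltage", positive = TRUE)
  } else {
    if (any(components)) {
      abort(paste(
        "Provide `end_to_end` or the component fields",
        "(`sensitivity`, `gain`, `adc_peak_voltage`), not both."
      ))
    }
    stopifnot_scalar(end_to_end, "end_to_end")
  }
  if (!is.null(frequency_response)) {
    frequency_response <- validate_frequency_response(frequency_response)
  }
  structure(
    list(
      domain = domain,
      p_ref = if (domain == "air") 20 else 1,
      sensitivity = sensitivity,
      gain = gain,
      adc_peak_voltage = adc_peak_voltage,
      end_to_end = end_to_end,
      frequency_response = frequency_response
    ),
    class = "cal_spec"
  )
}

validate_frequency_response <- function(fr) {
  fr <- tibble::as_tibble(fr)
  if (!all(c("frequency", "correction_db") %in% names(fr))) {
    abort("`frequency_response` needs columns `frequency` and `correction_db`.")
  }
  if (nrow(fr) < 1L || any(diff(fr$frequency) <= 0)) {
    abort("`frequency_response` frequencies must be strictly increasing.")
  }
  if (any(fr$frequency <= 0)) {
    abort("`frequency_response` frequencies must be positive.")
  }
  fr
}

#' @export
print.cal_spec <- function(x, ...) {
  cat(sprintf("<cal_spec> domain: %s (p_ref = %g uPa)\n", x$domain, x$p_ref))
  if (is.null(x$end_to_end)) {
    cat(sprintf(
      "  M = %g dB re 1 V/uPa, G = %g dB, ADC peak = %g V -> S = %g dB re FS/uPa\n",
      x$sensitivity, x$gain, x$adc_peak_voltage, combined_sensitivity(x)
    ))
  } else {
    cat(sprintf("  end-to-end S = %g dB re FS/uPa\n", x$end_to_end))
  }
  if (!is.null(x$frequency_response)) {
    cat(sprintf(
      "  frequency response: %d points, %g-%g Hz\n",
      nrow(x$frequency_response), min(x$frequency_response$frequency),
      max(x$frequency_response$frequency)
    ))
  }
  invisible(x)
}

#' Combined system sensitivity
#'
#' Collapses the calibration chain to a single sensitivity
#' `S = M + G - 20*log10(adc_peak_voltage)` in dB re full-scale per uPa, or
#' returns the measured end-to-end sensitivity verbatim.
#'
#' @param spec A [cal_spec()].
#' @return S in dB re full-scale per uPa.
#' @export
combined_sensitivity <- function(spec) {
  stopifnot(inherits(spec, "cal_spec"))
  if (!is.null(spec$end_to_end)) return(spec$end_to_end)
  spec$sensitivity + spec$gain - 20 * log10(spec$adc_peak_voltage)
}

#' Convert normalized audio samples to absolute sound pressure
#'
#' Reverses the acquisition chain: removes the segment-mean DC offset (an
#' acquisition artefact that would otherwise corrupt low-frequency PSD bins)
#' and scales by the inverse combined sensitivity, giving pressure in uPa:
#' `p[n] = (x[n] - mean(x)) * 10^(-S/20)`.
#'
#' @param seg An [audio_segment()].
#' @param spec A [cal_spec()].
#' @param demean Subtract the segment mean before scaling (default `TRUE`).
#' @return A [pressure_series()] carrying the domain's reference pressure and
#'   the segment's clipped fraction.
#' @export
apply_calibration <- function(seg, spec, demean = TRUE) {
  stopifnot(inherits(seg, "audio_segment"), inherits(spec, "cal_spec"))
  s <- combined_sensitivity(spec)
  x <- seg$samples
  if (demean && length(x)) x <- x - mean(x)
  pressure_series(
    x * 10^(-s / 20),
    sample_rate = seg$sample_rate,
    start_time = seg$start_time,
    p_ref = spec$p_ref,
    clipped_fraction = seg$clipped_fraction
  )
}

#' Apply a frequency-dependent response correction to spectrum levels
#'
#' Transducer sensitivity and pre-amplifier gain often vary with frequency.
#' This subtracts the system's relative response curve — interpolated
#' linearly in dB against log10 frequency, matching how response curves are
#' tabulated on log-frequency datasheets — from spectrum levels, bin by bin.
#' Frequencies outside the curve's range are clamped to the end values with
#' a warning.
#'
#' @param levels Numeric vector (or matrix with one row per frequency) of
#'   spectrum levels in dB.
#' @param frequencies Frequencies (Hz) of the levels.
#' @param spec A [cal_spec()] with a `frequency_response`.
#' @return Corrected levels, same shape as `levels`.
#' @export
apply_frequency_response <- function(levels, frequencies, spec) {
  stopifnot(inherits(spec, "cal_spec"))
  fr <- spec$frequency_response
  if (is.null(fr)) abort("`spec` has no `frequency_response` curve.")
  corr <- frequency_response_at(spec, frequencies, warn_extrapolation = TRUE)
  if (is.matrix(levels)) {
    if (nrow(levels) != length(frequencies)) {
      abort("`levels` must have one row per frequency.")
    }
    return(levels - corr)
  }
  if (length(levels) != length(frequencies)) {
    abort("`levels` and `frequencies` must have the same length.")
  }
  levels - corr
}

# interpolate the response curve at arbitrary frequencies (dB vs log10 f),
# clamping outside the tabulated range
frequency_response_at <- function(spec, frequencies, warn_extrapolation = FALSE) {
  fr <- spec$frequency_response
  if (is.null(fr)) return(rep(0, length(frequencies)))
  f <- pmax(frequencies, min(fr$frequency) * 1e-6) # guard the 0-Hz bin
  outside <- frequencies > max(fr$frequency) |
    (frequencies < min(fr$frequency) & frequencies > 0)
  if (warn_extrapolation && any(outside)) {
    warn(sprintf(
      "%d analysis frequencies outside the response curve range (%g-%g Hz); clamping to end values.",
      sum(outside), min(fr$frequency), max(fr$frequency)
    ))
  }
  if (nrow(fr) == 1L) return(rep(fr$correction_db, length(frequencies)))
  approx(log10(fr$frequency), fr$correction_db, xout = log10(f),
         rule = 2)$y
}

#' Read a calibration specification from a JSON file
#'
#' The file is a flat key-value object with the fields of [cal_spec()]. A
#' `frequency_response` entry may be inline (`frequency` and `correction_db`
#' arrays) or the path of a two-column CSV (`frequency,correction_db` in Hz
#' and dB), resolved relative to the JSON file.
#'
#' @param path Path to a JSON calibration file.
#' @return A [cal_spec()].
#' @export
read_cal_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fr <- raw$frequency_response
  if (is.character(fr) && length(fr) == 1L) {
    fr_path <- if (file.exists(fr)) fr else file.path(dirname(path), fr)
    fr <- utils::read.csv(fr_path)
  }
  if (!is.null(fr)) fr <- tibble::as_tibble(as.data.frame(fr))
  cal_spec(
    domain = raw$domain %||% "water",
    sensitivity = raw$sensitivity,
    gain = raw$gain,
    adc_peak_voltage = raw$adc_peak_voltage,
    end_to_end = raw$end_to_end,
    frequency_response = fr
  )
}
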