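# Statistical characterisation of level distributions. All statistics work
# on dB-domain inputs except rms_average, which averages in the power domain
# (the L_eq-style mean) before converting back to dB.

#' Power-domain (RMS) average of decibel levels
#'
#' The mean of the squared sound pressure computed before conversion to dB:
#' `10*log10(mean(10^(L/10)))`. This is the L_eq-style average and is >= the
#' arithmetic mean of the dB values (Jensen's inequality); with intermittent
#' high-amplitude events it can exceed the 95th percentile, so it should be
#' read alongside the median and mode.
#'
#' @param levels Numeric vector of dB levels.
#' @return RMS level in dB.
#' @export
#' @examples
#' rms_average(c(60, 70)) # 67.40 dB, not 65
rms_average <- function(levels) {
  levels <- levels[is.finite(levels)]
  if (length(levels) == 0L) abort("`levels` has no finite values.")
  10 * log10(mean(10^(levels / 10)))
}

#' Percentile levels
#'
#' Empirical quantiles of a level sample, with linear interpolation between
#' order statistics ([stats::quantile()] type 7).
#'
#' @param levels Numeric vector of dB levels.
#' @param probs Percentages in \[0, 100\].
#' @return A tibble with columns `percentile` and `level`.
#' @export
percentile_levels <- function(levels, probs = c(1, 5, 50, 95, 99)) {
  levels <- levels[is.finite(levels)]
  if (length(levels) == 0L) abort("`levels` has no finite values.")
  if (any(probs < 0 | probs > 100)) abort("`probs` must lie in [0, 100].")
  tibble::tibble(
    percentile = probs,
    level = quantile(levels, probs / 100, type = 7, names = FALSE)
  )
}

#' Exceedance levels
#'
#' The level exceeded x% of the time: `L_x` equals the (100 - x)th
#' percentile, so the 95% exceedance level `L_95` is the 5th percentile.
#'
#' @param levels Numeric vector of dB levels.
#' @param x Exceedance percentages in \[0, 100\].
#' @return A tibble with columns `exceedance` (x) and `level`.
#' @export
#' @examples
#' exceedance_levels(rnorm(100, 60), 95) # the 5th percentile
exceedance_levels <- function(levels, x = c(5, 50, 95)) {
  out <- percentile_levels(levels, 100 - x)
  tibble::tibble(exceedance = x, level = out$level)
}

#' Modal level of a level distribution
#'
#' Centre of the histogram bin with the highest empirical probability
#' density; ties break toward the lower level. Because level distributions
#' in real habitats are often multimodal (and the mode then misleads), a
#' `multimodal` attribute is set when a second local density peak lies
#' within `second_peak_db` of the maximum (on a `10*log10` density ratio
#' scale).
#'
#' @param levels Numeric vector of dB levels.
#' @param bin_width Histogram bin width in dB (default 1).
#' @param second_peak_db Tolerance (dB, on the density ratio) under which a
#'   secondary peak flags multimodality; default 6.
#' @return The modal level (dB), with attributes `multimodal` (logical) and
#'   `n_peaks` (number of local density maxima).
#' @export
mode_level <- function(levels, bin_width = 1, second_peak_db = 6) {
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  levels <- levels[is.finite(levels)]
  if (length(levels) == 0L) abort("`levels` has no finite values.")
  h <- level_histogram(levels, bin_width)
  i_max <- which.max(h$density) # which.max takes the first (lower) tie
  peaks <- local_maxima(h$density)
  second <- setdiff(peaks, i_max)
  multimodal <- length(second) > 0 &&
    any(10 * log10(h$density[i_max] / h$density[second]) <= second_peak_db)
  structure(h$mid[i_max], multimodal = multimodal,
            n_peaks = length(peaks))
}

level_histogram <- function(levels, bin_width) {
  lo <- floor(min(levels) / bin_width) * bin_width
  hi <- ceiling(max(levels) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (max(levels) >= breaks[length(breaks)]) {
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  }
  counts <- tabulate(findInterval(levels, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  list(
    breaks = breaks,
    mid = head(breaks, -1L) + bin_width / 2,
    counts = counts,
    density = counts / (length(levels) * bin_width)
  )
}

# indices (first of each plateau run) of local maxima of a vector; a
# flat-topped peak counts once
local_maxima <- function(d) {
  r <- rle(d)
  k <- length(r$values)
  if (k == 1L) return(if (d[1L] > 0) 1L else integer(0))
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  run_is_peak <- r$values > 0 & r$values > left & r$values > right
  first_idx <- cumsum(c(1L, r$lengths[-k]))
  first_idx[run_is_peak]
}

#' Spectral probability density
#'
#' The empirical probability density of sound levels in each frequency band
#' of a PSD grid: for every frequency row, a normalized histogram of the dB
#' levels over time (units 1/dB). The SPD reveals modal structure, outliers,
#' and recording-system limits — a self-noise floor shows up as the lowest
#' populated level bins converging on the mode at floor-dominated
#' frequencies.
#'
#' @param grid A `psd_grid` with at least 2 time steps.
#' @param bin_width Level bin width in dB (default 1).
#' @return An `spd` object: a long tibble with columns `frequency`, `level`
#'   (bin centre, dB), `density` (1/dB) and `n` (samples per frequency).
#'   For each frequency, `sum(density) * bin_width == 1`.
#' @export
#' @examples
#' p <- synth_white_noise(60, duration = 30, sample_rate = 2000, seed = 1)
#' g <- psd_welch(p, segment_seconds = 1)
#' s <- spd(g)
#' dplyr::summarise(dplyr::group_by(s, frequency),
#'                  total = sum(density) * attr(s, "bin_width"))
spd <- function(grid, bin_width = 1) {
  stopifnot(inherits(grid, "psd_grid"))
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  if (length(grid$times) < 2L) {
    abort("SPD needs at least 2 time steps (density undefined for one).")
  }
  x <- grid$levels
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  mids <- head(breaks, -1L) + bin_width / 2
  n_t <- ncol(x)
  out <- purrr::map_dfr(seq_along(grid$frequencies), function(i) {
    counts <- tabulate(findInterval(x[i, ], breaks), nbins = length(mids))
    tibble::tibble(
      frequency = grid$frequencies[i],
      level = mids,
      density = counts / (n_t * bin_width),
      n = n_t
    )
  })
  structure(out, class = c("spd", class(out)), bin_width = bin_width,
            p_ref = grid$p_ref)
}

#' Summary statistics of a level sample
#'
#' One row of the averaging and spread metrics used for habitat
#' characterisation: power-domain RMS average, arithmetic dB mean, median
#' (L_50), mode, requested percentiles, and the boxplot five-number summary.
#'
#' @param levels Numeric vector of dB levels.
#' @param probs Percentiles to include (wide columns `p5`, `p95`, ...).
#' @param bin_width Histogram bin width for the mode (dB).
#' @return A one-row tibble.
#' @export
summary_stats <- function(levels, probs = c(5, 95), bin_width = 1) {
  levels <- levels[is.finite(levels)]
  if (length(levels) == 0L) abort("`levels` has no finite values.")
  q <- quantile(levels, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  m <- mode_level(levels, bin_width)
  out <- tibble::tibble(
    n = length(levels),
    rms_level = rms_average(levels),
    mean_db = mean(levels),
    median = q[3L],
    mode = as.numeric(m),
    multimodal = attr(m, "multimodal"),
    min = q[1L],
    q1 = q[2L],
    q3 = q[4L],
    max = q[5L]
  )
  if (length(probs)) {
    pl <- percentile_levels(levels, probs)
    wide <- stats::setNames(as.list(pl$level), paste0("p", probs))
    out <- dplyr::bind_cols(out, tibble::as_tibble(wide))
  }
  out
}

#' Per-frequency statistics of a PSD grid
#'
#' Computes, for every frequency of a stored PSD grid (no second pass over
#' the audio), the RMS level, median, mode and requested percentiles of the
#' level time series — the ingredients of the classic composite
#' percentile/SPD spectrum plot.
#'
#' @param grid A `psd_grid`.
#' @inheritParams summary_stats
#' @return A tibble with one row per frequency.
#' @export
spectrum_stats <- function(grid, probs = c(1, 5, 50, 95, 99),
                           bin_width = 1) {
  stopifnot(inherits(grid, "psd_grid"))
  purrr::map_dfr(seq_along(grid$frequencies), function(i) {
    dplyr::bind_cols(
      tibble::tibble(frequency = grid$frequencies[i]),
      summary_stats(grid$levels[i, ], probs = probs, bin_width = bin_width)
    )
  })
}

#' Temporal aggregation of level time series
#'
#' Groups a level time series (a `band_series`, a tidied `psd_grid`, or any
#' tibble with a `POSIXct` `time` column and a `level` column) by hour of
#' day, calendar day or month, and applies a statistic per frequency/band —
#' the machinery behind diel median plots and per-band boxplots. Hour of day
#' uses the recording time as parsed; no daylight-saving adjustment.
#'
#' @param x A `band_series`, `psd_grid`, or tibble with `time` (`POSIXct`)
#'   and `level` columns; optional `band`/`nominal`/`frequency` columns are
#'   used as grouping variables.
#' @param period `"hour"` (of day), `"day"` or `"month"`.
#' @param stat `"median"`, `"rms"`, `"percentiles"` or `"boxplot"`.
#' @param probs Percentages for `stat = "percentiles"`.
#' @return A tibble keyed by the period (and any band/frequency columns)
#'   with the statistic's columns: `median`; `rms_level`; percentile
#'   columns; or the boxplot five-number summary
#'   `min`, `q1`, `median`, `q3`, `max`.
#' @export
temporal_aggregate <- function(x, period = c("hour", "day", "month"),
                               stat = c("median", "rms", "percentiles",
                                        "boxplot"),
                               probs = c(5, 50, 95)) {
  period <- match.arg(period)
  stat <- match.arg(stat)
  if (inherits(x, "psd_grid")) x <- tidy(x)
  x <- tibble::as_tibble(x)
  if (!all(c("time", "level") %in% names(x))) {
    abort("`x` needs `time` and `level` columns.")
  }
  if (!inherits(x$time, "POSIXct")) {
    abort("Temporal aggregation needs absolute `POSIXct` timestamps; attach a start time when reading or generating the data.")
  }
  x$.key <- switch(period,
    hour = lubridate::hour(x$time),
    day = lubridate::as_date(x$time),
    month = lubridate::month(x$time)
  )
  group_cols <- intersect(c("band", "nominal", "center", "frequency"),
                          names(x))
  g <- dplyr::group_by(x, dplyr::across(dplyr::all_of(c(".key", group_cols))))
  out <- switch(stat,
    median = dplyr::summarise(g, median = stats::median(.data$level),
                              n = dplyr::n(), .groups = "drop"),
    rms = dplyr::summarise(g, rms_level = rms_average(.data$level),
                           n = dplyr::n(), .groups = "drop"),
    percentiles = dplyr::reframe(
      g, percentile_levels(.data$level, probs), n = dplyr::n()
    ),
    boxplot = dplyr::summarise(
      g,
      min = min(.data$level),
      q1 = quantile(.data$level, 0.25, type = 7, names = FALSE),
      median = stats::median(.data$level),
      q3 = quantile(.data$level, 0.75, type = 7, names = FALSE),
      max = max(.data$level),
      n = dplyr::n(),
      .groups = "drop"
    )
  )
  names(out)[names(out) == ".key"] <- period
  out
}
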