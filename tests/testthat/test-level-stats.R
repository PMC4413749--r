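test_that("rms_average works in the power domain", {
  expect_equal(rms_average(c(60, 60, 60)), 60)
  # hand arithmetic: 10*log10((1e6 + 1e7)/2) = 67.40363
  expect_equal(rms_average(c(60, 70)), 67.40363, tolerance = 1e-5)
  expect_error(rms_average(numeric(0)), "finite")
  expect_error(rms_average(c(NA, NaN)), "finite")
})

test_that("rms_average >= arithmetic dB mean (Jensen), equality for constants", {
  set.seed(51)
  for (i in 1:20) {
    lv <- rnorm(200, mean = 60, sd = runif(1, 0.5, 8))
    expect_gte(rms_average(lv), mean(lv))
  }
  expect_equal(rms_average(rep(42, 5)), mean(rep(42, 5)))
})

test_that("one loud window in a hundred drags the RMS average above the 95th percentile", {
  lv <- c(rep(60, 99), 100) # 1% of windows +40 dB
  p95 <- percentile_levels(lv, 95)$level
  expect_gt(rms_average(lv), p95)
})

test_that("percentiles interpolate order statistics; exceedance levels reverse them", {
  expect_equal(percentile_levels(1:100, 5)$level, 5.95) # type-7 by hand
  set.seed(52)
  lv <- rnorm(500, 60, 5)
  expect_equal(percentile_levels(lv, 50)$level, stats::median(lv))
  # L_95 is the 5th percentile
  expect_equal(exceedance_levels(lv, 95)$level,
               percentile_levels(lv, 5)$level)
  # monotone in order, bounded by min/max
  q <- percentile_levels(lv, c(0, 10, 50, 90, 100))$level
  expect_true(all(diff(q) >= 0))
  expect_equal(q[c(1, 5)], range(lv))
  expect_error(percentile_levels(lv, 101), "\\[0, 100\\]")
})

test_that("percentiles and SPD are equivariant under a constant dB offset", {
  set.seed(53)
  lv <- rnorm(300, 60, 4)
  expect_equal(percentile_levels(lv + 12, c(5, 50, 95))$level,
               percentile_levels(lv, c(5, 50, 95))$level + 12)

  p <- synth_white_noise(60, duration = 20, sample_rate = 1000, seed = 54)
  g <- psd_welch(p, segment_seconds = 1)
  g2 <- g
  g2$levels <- g$levels + 7 # a 7 dB gain change
  s1 <- spd(g, bin_width = 1)
  s2 <- spd(g2, bin_width = 1)
  m1 <- dplyr::filter(s1, density > 0)
  m2 <- dplyr::filter(s2, density > 0)
  expect_equal(m2$density, m1$density)
  expect_equal(m2$level, m1$level + 7)
})

test_that("mode_level picks the densest bin, breaking ties low, and flags bimodality", {
  expect_equal(as.numeric(mode_level(rep(55.2, 10), bin_width = 1)), 55.5)
  set.seed(55)
  uni <- rnorm(5000, 60, 3)
  m <- mode_level(uni, bin_width = 1)
  expect_lt(abs(as.numeric(m) - stats::median(uni)), 1)
  expect_false(attr(m, "multimodal"))

  bi <- c(rnorm(7000, 50, 1.5), rnorm(3000, 80, 1.5)) # 70% / 30% mixture
  mb <- mode_level(bi, bin_width = 1)
  expect_lt(abs(as.numeric(mb) - 50), 1.5) # mode sits in the 50 dB cluster
  expect_true(attr(mb, "multimodal"))
  expect_error(mode_level(numeric(0)), "finite")
})

test_that("SPD densities integrate to 1 per frequency and need >= 2 time steps", {
  p <- synth_white_noise(60, duration = 30, sample_rate = 2000, seed = 56)
  g <- psd_welch(p, segment_seconds = 1)
  s <- spd(g, bin_width = 1)
  bw <- attr(s, "bin_width")
  integrals <- dplyr::summarise(dplyr::group_by(s, frequency),
                                total = sum(density) * bw)$total
  expect_equal(integrals, rep(1, length(integrals)))
  expect_true(all(s$density >= 0))

  g1 <- psd_welch(p, segment_seconds = 1, average_seconds = 30)
  expect_error(spd(g1), "2 time steps")
})

test_that("SPD of stationary Gaussian noise follows the dB chi-square law", {
  # rectangular window, no overlap, no averaging: each bin's periodogram is
  # density * chisq_2 / 2; compare the dB levels at one bin against a
  # Monte-Carlo sample of the closed-form distribution
  fs <- 2000
  density_db <- 60
  p <- synth_white_noise(density_db, duration = 500, sample_rate = fs,
                         seed = 57)
  g <- psd_welch(p, segment_length = 1000, window = "rectangular",
                 overlap = 0)
  bin <- 100L
  observed <- g$levels[bin, ]
  set.seed(58)
  reference <- density_db + 10 * log10(stats::rchisq(4000, df = 2) / 2)
  ks <- suppressWarnings(stats::ks.test(observed, reference))
  expect_gt(ks$p.value, 0.01)
})

test_that("hour-of-day aggregation recovers a synthetic diel step", {
  st <- as.POSIXct("2013-10-19 00:00:00", tz = "UTC")
  # 24 h at a coarse rate; +10 dB during hours 6-18
  p <- synth_diel_cycle(60, 10, duration = 24 * 3600, sample_rate = 20,
                        day_hours = c(6, 18), start_time = st, seed = 59)
  b <- broadband_spl(p, segment_seconds = 10, overlap = 0)
  agg <- temporal_aggregate(
    tibble::tibble(time = b$time, level = b$spl), "hour", "median"
  )
  expect_equal(nrow(agg), 24L)
  day <- agg$median[agg$hour %in% 6:17]
  night <- agg$median[agg$hour %in% c(0:5, 18:23)]
  expect_equal(mean(day) - mean(night), 10, tolerance = 1)
})

test_that("aggregating a single group equals the ungrouped statistic; boxplots are ordered", {
  st <- as.POSIXct("2014-06-01 03:00:00", tz = "UTC")
  set.seed(60)
  tbl <- tibble::tibble(
    time = st + seq(0, 3599, by = 10), # all within hour 3
    level = rnorm(360, 70, 5)
  )
  agg <- temporal_aggregate(tbl, "hour", "median")
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$median, stats::median(tbl$level))
  expect_equal(temporal_aggregate(tbl, "hour", "rms")$rms_level,
               rms_average(tbl$level))

  bx <- temporal_aggregate(tbl, "hour", "boxplot")
  expect_true(bx$min <= bx$q1 && bx$q1 <= bx$median &&
                bx$median <= bx$q3 && bx$q3 <= bx$max)

  expect_error(
    temporal_aggregate(tibble::tibble(time = 1:5, level = 1:5), "hour"),
    "POSIXct"
  )
})

test_that("summary_stats and spectrum_stats expose consistent order statistics", {
  set.seed(61)
  lv <- rnorm(400, 65, 6)
  st <- summary_stats(lv, probs = c(5, 95))
  expect_true(st$min <= st$q1 && st$q1 <= st$median && st$median <= st$q3 &&
                st$q3 <= st$max)
  expect_gte(st$rms_level, st$mean_db)
  expect_equal(st$p5, percentile_levels(lv, 5)$level)

  p <- synth_white_noise(60, duration = 20, sample_rate = 1000, seed = 62)
  g <- psd_welch(p, segment_seconds = 1)
  sp <- spectrum_stats(g, probs = c(5, 95))
  expect_equal(nrow(sp), length(g$frequencies))
  expect_true(all(sp$p5 <= sp$p95))
})
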