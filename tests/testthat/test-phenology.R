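test_that("intensity series normalizes to [0,1] and honors masks", {
  t0 <- as.POSIXct("2012-06-01 00:00:00", tz = "UTC")
  tt <- t0 + (0:4) * 30
  G <- rbind(c(0, 0, 2, 0, 0), c(0, 0, 3, 0, 0))
  s <- intensity_series(G, time = tt)
  expect_equal(s$value, c(0, 0, 1, 0, 0))
  # doubling the grid leaves the normalized series unchanged
  expect_equal(intensity_series(2 * G, time = tt)$value, s$value)
  # masking the peak: next-largest column becomes 1 (5-column toy:
  # col sums 1,2,5,4,0 -> mask col 3 -> (1,2,0,4,0)/unmasked max 4, min 0)
  G2 <- rbind(c(1, 2, 5, 4, 0))
  s2 <- intensity_series(G2, time = tt,
                         mask_ranges = list(c(tt[3], tt[3])))
  expect_equal(s2$value, c(0.25, 0.5, 0, 1, 0))
  expect_warning(intensity_series(matrix(1, 2, 5), time = tt), "constant")
  expect_error(intensity_series(-G, time = tt), "nonnegative")
})

test_that("autocorrelation is 1 at lag zero and symmetric by construction", {
  set.seed(1)
  s <- make_series(runif(600))
  lc <- lag_correlation(s, max_lag = 1800)
  expect_equal(lc$score[lc$lag == 0], 1)
  full <- lag_correlation(s, s, max_lag = 1800)
  expect_equal(full$score, rev(full$score), tolerance = 1e-12)
})

test_that("a 24-h sinusoid peaks at integer multiples of one day", {
  fpd <- 2880                                  # 30-s frames per day
  v <- 1 + sin(2 * pi * (1:(4 * fpd)) / fpd)
  lc <- lag_correlation(make_series(v), max_lag = 2.5 * 86400,
                        envelope_window = 86400)
  sc <- lc$score
  i1 <- which(lc$lag == 86400)
  expect_true(sc[i1] >= max(sc[seq.int(i1 - 5, i1 + 5)]) - 1e-9)
  expect_gt(sc[i1], 0.99)
  i2 <- which(lc$lag == 2 * 86400)
  expect_gt(sc[i2], 0.99)
  # envelope dominates the scores wherever both are defined
  ok <- !is.na(lc$envelope) & !is.na(lc$score)
  expect_true(all(lc$envelope[ok] >= lc$score[ok] - 1e-12))
  # reported peaks are a subset of envelope local maxima
  if (nrow(lc$peaks)) {
    for (l in lc$peaks$lag) {
      i <- which(lc$lag == l)
      expect_true(lc$envelope[i] >= lc$envelope[i - 1] &&
                    lc$envelope[i] >= lc$envelope[i + 1])
    }
  }
})

test_that("cross-correlation recovers a known time shift", {
  fpd <- 2880
  set.seed(2)
  base <- 1 + sin(2 * pi * (1:(5 * fpd)) / fpd) + rnorm(5 * fpd, 0, 0.05)
  shift <- 480                                  # 4 h in 30-s frames
  a <- make_series(base[seq_len(4 * fpd)])
  b <- make_series(base[seq_len(4 * fpd) + shift])
  # b leads a by 4 h: correlating a(t) with b(t + lag) peaks at -4 h,
  # correlating b against a peaks at +4 h
  lc <- lag_correlation(b, a, max_lag = 12 * 3600, envelope_window = 3600)
  peak_lag <- lc$lag[which.max(lc$score)]
  expect_lte(abs(peak_lag - shift * 30), 30)
})

test_that("gappy series drop lags with insufficient overlap", {
  v <- c(runif(150), rep(NA, 150), runif(100))
  lc <- lag_correlation(make_series(v), max_lag = 150 * 30)
  expect_equal(lc$score[lc$lag == 0], 1)       # lag 0 still well covered
  expect_true(is.na(lc$score[lc$lag == 120 * 30]))  # < 50% overlap
})

test_that("cycle models bin, summarize and interpolate the fold", {
  # constant series: every statistic 0.5, spline identically 0.5
  fpd <- 288                                    # 5-min frames for speed
  t0 <- as.POSIXct("2012-06-01 00:00:00", tz = "UTC")
  s <- make_series(rep(0.5, 3 * fpd), dt = 300)
  cm <- cycle_model(s, "diurnal")
  expect_true(all(abs(cm$q - 0.5) < 1e-12))
  expect_true(all(abs(cm$fun(seq(0, 24, by = 0.1)) - 0.5) < 1e-9))
  expect_error(cycle_model(make_series(runif(100), dt = 300), "diurnal"),
               "2")
})

test_that("a dusk chorus yields a diurnal spline peaking near 20:00", {
  src <- source_spec("fish", band = c(500, 3000), kind = "chorus",
                     schedule = diurnal_schedule(20, 1.5),
                     amplitude_jitter = 0.2, event_rate = 0.95)
  cfg <- scene_config(list(src), duration_days = 4, n_freq = 24, seed = 5)
  sc <- generate_ltsa_scene(cfg)
  s <- intensity_series(sc$per_source[[1]], time = sc$times)
  cm <- cycle_model(s, "diurnal")
  # the scheduled dusk peak is recovered at the hour scale, and the spline
  # at 20:00 is essentially at its maximum
  expect_lt(abs(cm$peak - 20), 0.5)
  expect_gt(cm$fun(20), 0.95 * cm$fun(cm$peak))
})

test_that("lunar and seasonal folds recover the phase of slow cycles", {
  t0 <- as.POSIXct("2012-01-01 00:00:00", tz = "UTC")
  # hourly frames over 90 days, intensity following the synodic cycle
  tt <- t0 + (0:(90 * 24 - 1)) * 3600
  lun <- lunar_modulation(min_level = 0)(tt)
  s <- structure(list(time = tt, value = lun,
                      masked = rep(FALSE, length(tt)), source = "lunar"),
                 class = "intensity_series")
  cm <- cycle_model(s, "lunar")
  # peak at the new-moon anchor (phase 0, possibly wrapped)
  expect_lt(min(cm$peak, 29.530588 - cm$peak), 1.5)
  # seasonal: 2.2 years of 6-hourly frames peaking at day-of-year 180
  tt2 <- t0 + (0:(2.2 * 365 * 4 - 1)) * 21600
  doy <- as.numeric(difftime(
    tt2, as.POSIXct(paste0(format(tt2, "%Y"), "-01-01"), tz = "UTC"),
    units = "days"))
  v2 <- exp(-0.5 * ((doy - 180) / 25)^2)
  s2 <- structure(list(time = tt2, value = v2,
                       masked = rep(FALSE, length(tt2)), source = "seas"),
                  class = "intensity_series")
  cm2 <- cycle_model(s2, "seasonal")
  expect_lt(abs(cm2$peak - 180), 4)
  expect_equal(ceiling(cm2$peak / 7), 26, tolerance = 1)
})

test_that("cycle folding is invariant to interleaving identical cycles", {
  fpd <- 288
  day <- pmax(sin(2 * pi * (1:fpd) / fpd), 0)
  s2 <- make_series(rep(day, 2), dt = 300)
  s4 <- make_series(rep(day, 4), dt = 300)
  m2 <- cycle_model(s2, "diurnal")
  m4 <- cycle_model(s4, "diurnal")
  expect_equal(m2$q, m4$q, tolerance = 1e-12)
  expect_equal(m2$peak, m4$peak)
})
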