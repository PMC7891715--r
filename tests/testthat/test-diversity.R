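test_that("event rules: threshold, 10-min merge boundary, 1-min discard", {
  dt <- 30
  # detections in frames 1-4 and 25-28; the silent gap is frames 5-24,
  # exactly 20 frames = 10 min: rule is 'split only when > 10 min', so the
  # two runs merge into one event
  v <- c(rep(0.9, 4), rep(0, 20), rep(0.9, 4))
  ev <- detect_events(make_series(v), threshold = 0.05)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_frames, 8)
  # one silent frame more: the gap exceeds 10 min and splits the event
  v2 <- c(rep(0.9, 4), rep(0, 21), rep(0.9, 4))
  ev2 <- detect_events(make_series(v2), threshold = 0.05)
  expect_equal(nrow(ev2), 2)
  # a single 30-s frame is shorter than 1 min and is discarded
  expect_equal(nrow(detect_events(make_series(c(0, 1, 0, 0)))), 0)
  # everything above threshold: exactly one event spanning the series
  ev3 <- detect_events(make_series(rep(0.5, 10)))
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$duration_min, 5)
  expect_error(detect_events(make_series(v), threshold = 0), "threshold")
  expect_error(detect_events(make_series(v), threshold = 1.5), "threshold")
})

test_that("event detection matches the brute-force oracle on random series", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(20:120, 1)
    v <- round(runif(n), 2) * rbinom(n, 1, 0.6)
    ev <- detect_events(make_series(v), threshold = 0.05)
    orc <- oracle_events(v, 30, 0.05, 600, 60)
    expect_equal(nrow(ev), length(orc))
    if (length(orc)) {
      expect_equal(attr(ev, "frames"),
                   lapply(orc, function(g) seq(g[1], g[length(g)])[
                     v[seq(g[1], g[length(g)])] >= 0.05]))
    }
  }
})

test_that("event detection commutes with time reversal", {
  set.seed(12)
  v <- round(runif(80), 2) * rbinom(80, 1, 0.5)
  ev_f <- detect_events(make_series(v), threshold = 0.05)
  ev_r <- detect_events(make_series(rev(v)), threshold = 0.05)
  expect_equal(nrow(ev_f), nrow(ev_r))
  f_fwd <- attr(ev_f, "frames")
  f_rev <- lapply(rev(attr(ev_r, "frames")),
                  function(g) sort(81 - g))
  expect_equal(f_fwd, f_rev)
})

test_that("event spectra are pooled means, min-max normalized", {
  v <- c(rep(0.9, 4), rep(0, 30), rep(0.6, 4))
  G <- matrix(0, 3, 38)
  G[, 1:4] <- c(1, 2, 3)
  G[, 35:38] <- c(5, 1, 0)
  ev <- detect_events(make_series(v), list(P = G), threshold = 0.05)
  sp <- attr(ev, "spectra")
  expect_equal(sp[1, ], c(0, 0.5, 1))          # (1,2,3) normalized
  expect_equal(sp[2, ], c(1, 0.2, 0))          # (5,1,0) normalized
})

test_that("dispersion score R follows its defining identities", {
  g <- make_grouped_spectra()
  scan <- cluster_events(g$X, k_range = 1:6, seed = 2)
  rc <- scan$r_curve
  expect_equal(rc$R[rc$k == 1], 0)
  # recomputing R from the stored dispersions matches exactly
  for (res in scan$results)
    expect_equal(res$R, 100 * (1 - sum(res$D_i) / res$D1),
                 tolerance = 1e-9)
  # k = n gives R = 100 (every point its own centroid)
  small <- g$X[seq(1, 60, by = 6), ]
  scan_n <- cluster_events(small, k_range = nrow(small), seed = 3)
  expect_equal(scan_n$r_curve$R, 100, tolerance = 1e-9)
  # R non-decreasing in k for best-of-restarts k-means
  expect_true(all(diff(rc$R) >= -0.5))
})

test_that("well-separated spectrum groups are recovered exactly at k = 3", {
  g <- make_grouped_spectra()
  scan <- cluster_events(g$X, k_range = 2:5, seed = 4)
  res3 <- scan$results[[which(scan$k_range == 3)]]
  expect_gte(res3$R, 90)
  expect_equal(mclust::adjustedRandIndex(res3$cluster, g$labels), 1)
  expect_error(cluster_events(g$X, k_range = 1000), "exceeds")
})

test_that("choose_k takes the threshold rule, then the elbow fallback", {
  expect_equal(as.integer(choose_k(data.frame(k = 1:3, R = c(0, 95, 97)),
                                   93)), 2L)
  one <- choose_k(data.frame(k = 3, R = 94), 93)
  expect_equal(as.integer(one), 3L)
  expect_warning(k <- choose_k(data.frame(k = 1:5,
                                          R = c(0, 60, 80, 85, 87)), 93),
                 "elbow")
  expect_equal(as.integer(k), 2L)              # curvature largest after 2
  expect_error(choose_k(data.frame(k = integer(0), R = numeric(0))),
               "empty")
})

test_that("cluster summaries are duration-weighted probabilities", {
  t0 <- as.POSIXct("2012-06-01 20:00:00", tz = "UTC")
  # one 2-h event at 20:00-22:00 (240 x 30-s frames)
  v <- rep(0.9, 240)
  G <- matrix(1, 4, 240)
  s <- structure(list(time = t0 + (0:239) * 30, value = v,
                      masked = rep(FALSE, 240), source = "toy"),
                 class = "intensity_series")
  ev <- detect_events(s, list(P = G + runif(960)), threshold = 0.05)
  sm <- summarize_clusters(ev, list(cluster = rep(1L, nrow(ev))))
  hourly <- sm$clusters[[1]]$hourly
  expect_equal(hourly[21], 0.5)                # hour 20 (1-indexed 21)
  expect_equal(hourly[22], 0.5)
  expect_equal(sum(hourly), 1)
  expect_equal(sum(sm$clusters[[1]]$monthly), 1)
  expect_equal(sm$clusters[[1]]$monthly[6], 1) # all in June
})

test_that("two equal events in different months split monthly mass 50/50", {
  t0 <- as.POSIXct("2012-06-30 23:00:00", tz = "UTC")
  tt <- t0 + (0:479) * 30                      # crosses into July
  v <- c(rep(0.9, 120), rep(0, 240), rep(0.9, 120))
  G <- matrix(1, 2, 480)
  s <- structure(list(time = tt, value = v, masked = rep(FALSE, 480),
                      source = "toy"), class = "intensity_series")
  ev <- detect_events(s, list(P = G), threshold = 0.05)
  expect_equal(nrow(ev), 2)
  sm <- summarize_clusters(ev, list(cluster = c(1L, 1L)))
  expect_equal(sm$clusters[[1]]$monthly[6], 0.5)
  expect_equal(sm$clusters[[1]]$monthly[7], 0.5)
})
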