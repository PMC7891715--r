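test_that("a degenerate always-on source gives identical columns, all active", {
  src <- source_spec("hum", band = c(100, 900), kind = "chorus",
                     schedule = constant_schedule(1),
                     amplitude_jitter = 0, event_rate = 1)
  cfg <- scene_config(list(src), duration_days = 0.05, n_freq = 16,
                      seed = 1)
  sc <- generate_ltsa_scene(cfg)
  expect_true(all(sc$grid$P == sc$grid$P[, 1]))
  expect_true(all(sc$truth$labels == 1L))
})

test_that("the mixture is the elementwise sum of per-source grids", {
  cfg <- tiny_two_source_scene(duration_days = 1)
  sc <- generate_ltsa_scene(cfg)
  expect_equal(sc$grid$P, Reduce(`+`, sc$per_source))
  # disjoint bands: per-source column sums add up
  expect_equal(colSums(sc$grid$P),
               colSums(sc$per_source[[1]]) + colSums(sc$per_source[[2]]))
  expect_true(all(sc$grid$P >= 0))
})

test_that("a diurnal source's true intensity is 24-h periodic", {
  src <- source_spec("chorus", band = c(500, 3000), kind = "chorus",
                     schedule = diurnal_schedule(20, 2),
                     amplitude_jitter = 0.1, event_rate = 1)
  cfg <- scene_config(list(src), duration_days = 7, n_freq = 24, seed = 2)
  sc <- generate_ltsa_scene(cfg)
  v <- sc$truth$intensities[, 1]
  frames_per_day <- 86400 / cfg$clip_seconds
  # autocorrelation has a local maximum at lag 24 h
  ac <- stats::acf(v, lag.max = frames_per_day * 1.2, plot = FALSE)$acf
  lag24 <- frames_per_day + 1
  expect_true(ac[lag24] > ac[lag24 - 60] && ac[lag24] > ac[lag24 + 60])
  # the dominant nonzero DFT frequency is 1 cycle / day
  sp <- Mod(stats::fft(v - mean(v)))[2:(length(v) %/% 2)]
  expect_equal(which.max(sp), 7L)            # 7 cycles over 7 days
})

test_that("scene generation is deterministic and validates its inputs", {
  cfg <- tiny_two_source_scene(duration_days = 0.5)
  a <- generate_ltsa_scene(cfg)
  b <- generate_ltsa_scene(cfg)
  expect_identical(a$grid$P, b$grid$P)
  expect_identical(a$truth, b$truth)
  expect_error(scene_config(list(), duration_days = 1), "at least one")
  expect_error(scene_config(list(1), duration_days = 1), "source_spec")
  src <- source_spec("s", band = c(100, 200))
  expect_error(scene_config(list(src), duration_days = -1), "duration")
  # identical band profiles only warn
  cfg2 <- scene_config(list(src, source_spec("t", band = c(100, 200))),
                       duration_days = 0.02, n_freq = 8, fmax = 400,
                       seed = 1)
  expect_warning(generate_ltsa_scene(cfg2), "identical band profiles")
})

test_that("WAV scenes write one timestamped clip per frame", {
  cfg <- tiny_two_source_scene(duration_days = 1 / 24)  # 1 h = 120 clips
  d <- withr::local_tempdir()
  out <- generate_wav_scene(cfg, d)
  expect_equal(nrow(out$manifest), 86400 / 24 / cfg$clip_seconds)
  expect_true(all(file.exists(out$manifest$file)))
  expect_match(basename(out$manifest$file[1]), "^\\d{8}_\\d{6}\\.wav$")
  t1 <- parse_clip_time(out$manifest$file)
  expect_identical(t1, out$times)
})

test_that("WAV scenes are byte-reproducible and respect Nyquist", {
  src <- source_spec("quiet", band = c(100, 500), kind = "chorus",
                     schedule = constant_schedule(0.5))
  cfg <- scene_config(list(src), duration_days = 2 / 2880, clip_seconds = 30,
                      sample_rate = 2000, n_freq = 8, seed = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_wav_scene(cfg, d1)
  m2 <- generate_wav_scene(cfg, d2)
  f1 <- m1$manifest$file[1]; f2 <- m2$manifest$file[1]
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  bad <- source_spec("ultra", band = c(100, 1500), kind = "chorus")
  cfgb <- scene_config(list(bad), duration_days = 1 / 2880,
                       sample_rate = 2000, seed = 1)
  expect_error(generate_wav_scene(cfgb, withr::local_tempdir()), "ultra")
})

test_that("a silent scene writes all-zero samples", {
  src <- source_spec("ghost", band = c(100, 400), kind = "chorus",
                     schedule = constant_schedule(0))
  cfg <- scene_config(list(src), duration_days = 1 / 2880,
                      sample_rate = 2000, seed = 4)
  d <- withr::local_tempdir()
  out <- generate_wav_scene(cfg, d)
  wav <- read_wav(out$manifest$file[1])
  expect_true(all(wav$samples == 0))
})

test_that("LTSA scenes plug into the LTSA pipeline types", {
  cfg <- tiny_two_source_scene(duration_days = 0.5)
  sc <- generate_ltsa_scene(cfg)
  expect_s3_class(sc$grid, "prewhitened_ltsa")
  fd <- fold(sc$grid, 30)
  expect_equal(fd$n_freq, cfg$n_freq)
  expect_equal(fd$n_time, ncol(sc$grid$P))
})
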