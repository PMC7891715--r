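#' Describe one synthetic sound source
#'
#' A source is an occupancy schedule over absolute time, a spectral band
#' profile, and a synthesis kind. The generator multiplies the schedule
#' (in `[0, 1]`), a Bernoulli activity thinning (`event_rate`), and
#' log-normal amplitude jitter into a per-frame amplitude, and spreads it
#' over frequency with the band profile.
#'
#' @param name Source label.
#' @param band `c(low, high)` frequency extent in Hz.
#' @param kind `"chorus"` (band-limited noise with optional spectral peaks),
#'   `"transient"` (decaying tone pulses in the band), `"tonal"`
#'   (fixed-frequency narrowband peaks), or `"broadband"` (decaying
#'   wideband profile).
#' @param schedule Function mapping a `POSIXct` vector to occupancy in
#'   `[0, 1]`; see [diurnal_schedule()], [constant_schedule()],
#'   [ar1_schedule()].
#' @param peaks Optional spectral peak frequencies (Hz) inside `band`.
#' @param amplitude_jitter Log-normal sigma of multiplicative amplitude
#'   noise (0 = none).
#' @param event_rate Probability that a scheduled frame is actually active,
#'   in `[0, 1]`.
#' @param level Overall relative level of the source.
#' @param band_profile Optional function `f(freq_hz) -> nonnegative
#'   amplitude` overriding the profile built from `kind`/`peaks`.
#' @return A `source_spec` object.
#' @export
source_spec <- function(name, band, kind = c("chorus", "transient", "tonal",
                                             "broadband"),
                        schedule = constant_schedule(),
                        peaks = NULL, amplitude_jitter = 0.2,
                        event_rate = 1, level = 1, band_profile = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1])
  if (event_rate < 0 || event_rate > 1) stop("event_rate must be in [0, 1]")
  if (amplitude_jitter < 0) stop("amplitude_jitter must be >= 0")
  structure(list(name = name, band = band, kind = kind, schedule = schedule,
                 peaks = peaks, amplitude_jitter = amplitude_jitter,
                 event_rate = event_rate, level = level,
                 band_profile = band_profile),
            class = "source_spec")
}

#' Occupancy schedules for synthetic sources
#'
#' `diurnal_schedule()` is a circular Gaussian bump in local time of day
#' (e.g. a dusk chorus peaking at 20:00), optionally multiplied by a slow
#' modulation such as [lunar_modulation()]. `constant_schedule()` is a fixed
#' occupancy. `ar1_schedule()` is an aperiodic, slowly varying occupancy
#' (first-order autoregressive in time, squashed to `[0, 1]`) for abiotic
#' sources such as wind and shipping; it is deterministic given its seed.
#'
#' @param peak_hour Hour of day (0-24) of maximum occupancy.
#' @param width_hours Gaussian sigma in hours.
#' @param modulation Optional function `f(times) -> [0, 1]` multiplied in.
#' @return A vectorized function `f(times) -> [0, 1]`.
#' @export
diurnal_schedule <- function(peak_hour, width_hours, modulation = NULL) {
  force(peak_hour); force(width_hours); force(modulation)
  function(times) {
    h <- as.numeric(times - as.POSIXct(format(times, "%Y-%m-%d"),
                                       tz = "UTC")) / 3600
    d <- abs(h - peak_hour)
    d <- pmin(d, 24 - d)                      # circular distance in hours
    v <- exp(-0.5 * (d / width_hours)^2)
    if (!is.null(modulation)) v <- v * modulation(times)
    v
  }
}

#' @rdname diurnal_schedule
#' @param level Constant occupancy in `[0, 1]`.
#' @export
constant_schedule <- function(level = 1) {
  force(level)
  function(times) rep(level, length(times))
}

#' @rdname diurnal_schedule
#' @param period_days Modulation period in days (29.53 for the synodic
#'   lunar cycle, 14.77 for the semilunar cycle).
#' @param min_level Occupancy at the modulation trough.
#' @param epoch Reference time of a modulation maximum (default the
#'   2000-01-06 18:14 UTC new moon).
#' @export
lunar_modulation <- function(period_days = 29.530588, min_level = 0.2,
                             epoch = as.POSIXct("2000-01-06 18:14:00",
                                                tz = "UTC")) {
  force(period_days); force(min_level); force(epoch)
  function(times) {
    ph <- as.numeric(difftime(times, epoch, units = "days")) / period_days
    min_level + (1 - min_level) * (1 + cos(2 * pi * ph)) / 2
  }
}

#' @rdname diurnal_schedule
#' @param mean_level Mean occupancy.
#' @param sd_level Standard deviation of the occupancy fluctuation.
#' @param correlation_hours Decorrelation time scale in hours.
#' @param seed Seed of the schedule's own (private) random stream.
#' @export
ar1_schedule <- function(mean_level = 0.3, sd_level = 0.25,
                         correlation_hours = 6, seed = 99) {
  force(mean_level); force(sd_level); force(correlation_hours); force(seed)
  function(times) {
    n <- length(times)
    dt <- if (n > 1) as.numeric(difftime(times[2], times[1],
                                         units = "hours")) else 1
    rho <- exp(-dt / correlation_hours)
    .with_seed(seed, {
      e <- stats::rnorm(n)
      z <- stats::filter(e * sqrt(1 - rho^2), rho, "recursive",
                         init = stats::rnorm(1))
      pmin(pmax(mean_level + sd_level * as.numeric(z), 0), 1)
    })
  }
}

## evaluate a source's spectral envelope on a frequency grid (max = level)
.band_profile <- function(src, freq) {
  if (!is.null(src$band_profile)) {
    v <- pmax(src$band_profile(freq), 0)
  } else {
    lo <- src$band[1]; hi <- src$band[2]
    width <- hi - lo
    v <- switch(src$kind,
      chorus = {
        inb <- freq >= lo & freq <= hi
        base <- ifelse(inb, 0.35 * sin(pi * (freq - lo) / width)^0.5, 0)
        if (!is.null(src$peaks))
          for (p in src$peaks)
            base <- base + exp(-0.5 * ((freq - p) / (0.06 * p))^2)
        base
      },
      transient = {
        inb <- freq >= lo & freq <= hi
        ifelse(inb, 0.4 + 0.6 * (freq - lo) / width, 0) *
          ifelse(inb, sin(pi * pmin((freq - lo) / (0.15 * width), 1) / 2), 0)
      },
      tonal = {
        base <- numeric(length(freq))
        pk <- src$peaks %||% mean(src$band)
        bw <- max(stats::median(diff(freq)), 1) * 1.2
        for (p in pk) base <- base + exp(-0.5 * ((freq - p) / bw)^2)
        base
      },
      broadband = {
        inb <- freq >= lo & freq <= hi
        ifelse(inb, (1 + (freq - lo) / (0.25 * width))^-1, 0)
      })
  }
  if (max(v) > 0) v <- v / max(v)
  v * src$level
}

#' Configure a synthetic soundscape scene
#'
#' Bundles the sources, extent and resolution of a synthetic scene. With a
#' fixed `seed` the generated outputs are bit-reproducible.
#'
#' @param sources List of [source_spec()] objects (at least one).
#' @param duration_days Scene length in days (> 0).
#' @param clip_seconds Clip/frame duration in seconds (default 30).
#' @param sample_rate Sampling rate in Hz for waveform synthesis (default
#'   16 kHz; the frequency axis of the LTSA-domain generator is capped at
#'   Nyquist).
#' @param n_freq Number of frequency bins for the LTSA-domain generator.
#' @param fmax Upper frequency of the LTSA axis (default Nyquist).
#' @param start Scene start time (UTC).
#' @param noise_floor_profile Optional function `f(freq) -> amplitude` of
#'   the stationary background used in waveform synthesis (the LTSA-domain
#'   generator is background-free, i.e. already prewhitened).
#' @param noise_floor_level Relative level of that background.
#' @param activity_floor A frame counts as truly active for a source when
#'   its energy exceeds this fraction of the source's maximum (default 0.05,
#'   matching the event-detection threshold convention).
#' @param seed Integer seed.
#' @return A `scene_config` object.
#' @export
scene_config <- function(sources, duration_days, clip_seconds = 30,
                         sample_rate = 16000, n_freq = 64, fmax = NULL,
                         start = as.POSIXct("2012-06-01 00:00:00",
                                            tz = "UTC"),
                         noise_floor_profile = NULL,
                         noise_floor_level = 0.05,
                         activity_floor = 0.05, seed = 1) {
  if (!length(sources)) stop("a scene needs at least one source")
  if (!all(vapply(sources, inherits, logical(1), "source_spec")))
    stop("sources must be source_spec objects")
  if (duration_days <= 0) stop("duration_days must be > 0")
  if (clip_seconds <= 0) stop("clip_seconds must be > 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  fmax <- fmax %||% (sample_rate / 2)
  structure(list(sources = sources, duration_days = duration_days,
                 clip_seconds = clip_seconds, sample_rate = sample_rate,
                 n_freq = n_freq, fmax = fmax, start = start,
                 noise_floor_profile = noise_floor_profile,
                 noise_floor_level = noise_floor_level,
                 activity_floor = activity_floor, seed = seed),
            class = "scene_config")
}

## per-frame amplitudes for all sources: schedule x Bernoulli(event_rate)
## x log-normal jitter; one matrix (frames x sources)
.scene_amplitudes <- function(config) {
  n <- round(config$duration_days * 86400 / config$clip_seconds)
  times <- config$start + (seq_len(n) - 1) * config$clip_seconds
  S <- length(config$sources)
  A <- matrix(0, n, S)
  .with_seed(config$seed, {
    for (s in seq_len(S)) {
      src <- config$sources[[s]]
      sched <- pmin(pmax(src$schedule(times), 0), 1)
      act <- if (src$event_rate < 1)
        stats::rbinom(n, 1, src$event_rate) else rep(1, n)
      jit <- if (src$amplitude_jitter > 0)
        exp(stats::rnorm(n, 0, src$amplitude_jitter)) else rep(1, n)
      A[, s] <- sched * act * jit
    }
  })
  list(times = times, A = A)
}

#' Generate a synthetic prewhitened LTSA with ground truth
#'
#' Builds an additive mixture grid directly in the LTSA domain: each source
#' contributes `amplitude(t) * band_profile(f)`, with source-specific
#' periodic schedules, Bernoulli activity thinning, and log-normal jitter.
#' No background is added (the grid emulates an already prewhitened LTSA).
#' Ground-truth labels mark frames where a source's true integrated energy
#' exceeds `activity_floor` of its maximum.
#'
#' @param config A [scene_config()].
#' @return An `ltsa_scene`: list with `grid` (a `prewhitened_ltsa`),
#'   `per_source` (list of per-source grids), `truth` (list with binary
#'   `labels` and true `intensities`, frames x sources), `times`, `freq`
#'   and `config`.
#' @export
generate_ltsa_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  freq <- seq(config$fmax / config$n_freq, config$fmax,
              length.out = config$n_freq)
  profiles <- vapply(config$sources, .band_profile, numeric(config$n_freq),
                     freq = freq)
  if (ncol(profiles) > 1) {
    pn <- sweep(profiles, 2, pmax(sqrt(colSums(profiles^2)), 1e-300), "/")
    gram <- crossprod(pn)
    if (any(gram[upper.tri(gram)] > 1 - 1e-12))
      warning("two sources have identical band profiles")
  }
  amp <- .scene_amplitudes(config)
  S <- length(config$sources)
  per_source <- vector("list", S)
  for (s in seq_len(S))
    per_source[[s]] <- outer(profiles[, s], amp$A[, s])
  names(per_source) <- vapply(config$sources, `[[`, character(1), "name")
  M <- Reduce(`+`, per_source)
  intens <- vapply(per_source, colSums, numeric(length(amp$times)))
  labels <- sweep(intens, 2, pmax(apply(intens, 2, max), 1e-300), "/") >
    config$activity_floor
  grid <- structure(list(P = M, freq = freq, time = amp$times,
                         clip_seconds = config$clip_seconds,
                         noise_floor = rep(0, config$n_freq),
                         percentile = NA_real_,
                         units = "relative (synthetic, prewhitened)"),
                    class = "prewhitened_ltsa")
  structure(list(grid = grid, per_source = per_source,
                 truth = list(labels = labels * 1L, intensities = intens),
                 times = amp$times, freq = freq, config = config),
            class = "ltsa_scene")
}

## synthesize one clip's waveform for the active sources + background
.clip_waveform <- function(config, amps, profiles_fun, ns) {
  sr <- config$sample_rate
  x <- numeric(ns)
  nyq_bins <- ns %/% 2
  fgrid <- (seq_len(nyq_bins)) * sr / ns
  shape_noise <- function(profile_vals, gain) {
    spec <- complex(modulus = stats::rnorm(nyq_bins, 0, 1)^2 + 1e-9,
                    argument = stats::runif(nyq_bins, -pi, pi))
    spec <- spec / Mod(spec) * profile_vals
    full <- c(0, spec, rep(0, ns - nyq_bins - 1))
    full[seq.int(ns, ns - nyq_bins + 2)] <- Conj(spec[seq_len(nyq_bins - 1)])
    Re(stats::fft(full, inverse = TRUE)) / ns * gain
  }
  for (s in seq_along(config$sources)) {
    if (amps[s] <= 0) next
    src <- config$sources[[s]]
    pv <- profiles_fun[[s]](fgrid)
    if (src$kind == "transient") {
      npulse <- stats::rpois(1, 10)
      for (k in seq_len(npulse)) {
        t0 <- sample.int(ns - round(0.05 * sr), 1)
        dur <- round(stats::runif(1, 0.01, 0.05) * sr)
        f0 <- stats::runif(1, src$band[1], src$band[2])
        tt <- seq_len(dur)
        x[t0 + tt - 1] <- x[t0 + tt - 1] +
          amps[s] * exp(-5 * tt / dur) * sin(2 * pi * f0 * tt / sr)
      }
    } else {
      x <- x + shape_noise(pv, amps[s]) * sqrt(ns) * 0.15
    }
  }
  if (!is.null(config$noise_floor_profile)) {
    pv <- pmax(config$noise_floor_profile(fgrid), 0)
    if (max(pv) > 0) pv <- pv / max(pv)
    x <- x + shape_noise(pv, config$noise_floor_level) * sqrt(ns) * 0.15
  }
  x
}

#' Generate synthetic WAV clips with ground truth
#'
#' Writes one timestamped mono PCM clip per frame (`YYYYMMDD_HHMMSS.wav`).
#' Chorus-, tonal- and broadband-kind sources are synthesized as Gaussian
#' noise shaped in the frequency domain by their band profile; transient
#' sources as exponentially decaying tone pulses; an optional stationary
#' colored background is added. Only the time-frequency statistics of real
#' recordings are emulated, which is what the downstream LTSA pipeline
#' consumes.
#'
#' @param config A [scene_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (data.frame: file,
#'   iso_start_time, active_sources), `truth` (as in
#'   [generate_ltsa_scene()]) and `times`.
#' @export
generate_wav_scene <- function(config, out_dir) {
  stopifnot(inherits(config, "scene_config"))
  nyq <- config$sample_rate / 2
  for (src in config$sources)
    if (src$band[2] > nyq)
      stop("sample_rate too low for source '", src$name, "': band upper ",
           "edge ", src$band[2], " Hz exceeds Nyquist ", nyq, " Hz")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  amp <- .scene_amplitudes(config)
  ns <- round(config$clip_seconds * config$sample_rate)
  profiles_fun <- lapply(config$sources, function(src) {
    function(freq) .band_profile(src, freq)
  })
  files <- character(length(amp$times))
  active <- character(length(amp$times))
  nm <- vapply(config$sources, `[[`, character(1), "name")
  .with_seed(config$seed + 1L, {
    for (i in seq_along(amp$times)) {
      x <- .clip_waveform(config, amp$A[i, ], profiles_fun, ns)
      peak <- max(abs(x), 1)
      f <- file.path(out_dir, format(amp$times[i], "%Y%m%d_%H%M%S.wav"))
      write_wav(x / peak * min(peak, 1) * 0.9, config$sample_rate, f)
      files[i] <- f
      active[i] <- paste(nm[amp$A[i, ] > 0], collapse = ";")
    }
  })
  manifest <- data.frame(file = files,
                         iso_start_time = format(amp$times,
                                                 "%Y-%m-%dT%H:%M:%SZ"),
                         active_sources = active,
                         stringsAsFactors = FALSE)
  labels <- sweep(amp$A, 2, pmax(apply(amp$A, 2, max), 1e-300), "/") >
    config$activity_floor
  invisible(list(manifest = manifest,
                 truth = list(labels = labels * 1L, intensities = amp$A),
                 times = amp$times))
}

#' Reference synthetic soundscape
#'
#' The packaged study conditions: a dusk-peaking fish chorus confined to
#' 0.5-3 kHz with spectral peaks near 750 Hz and 2.5 kHz (center 20:00,
#' semilunar modulation), nocturnal cetacean transients at >= 4 kHz (center
#' 00:00, lunar modulation, sparser activity), an aperiodic broadband
#' abiotic source, and electrical noise with fixed-frequency tonal peaks.
#'
#' @param duration_days Scene length (default 7).
#' @param sources Subset of `c("abiotic", "fish", "cetacean", "electrical")`.
#' @param seed Integer seed.
#' @param ... Passed on to [scene_config()].
#' @return A `scene_config`.
#' @export
demo_scene <- function(duration_days = 7,
                       sources = c("abiotic", "fish", "cetacean",
                                   "electrical"),
                       seed = 1, ...) {
  sources <- match.arg(sources, several.ok = TRUE)
  pool <- list(
    abiotic = source_spec("abiotic", band = c(10, 6000), kind = "broadband",
                          schedule = ar1_schedule(mean_level = 0.35,
                                                  sd_level = 0.25,
                                                  correlation_hours = 6,
                                                  seed = seed + 101L),
                          amplitude_jitter = 0.3, event_rate = 1,
                          level = 1.1),
    fish = source_spec("fish", band = c(500, 3000), kind = "chorus",
                       peaks = c(750, 2500),
                       schedule = diurnal_schedule(20, 1.5,
                                                   lunar_modulation(14.765294,
                                                                    0.25)),
                       amplitude_jitter = 0.25, event_rate = 0.95,
                       level = 1),
    cetacean = source_spec("cetacean", band = c(4000, 7800),
                           kind = "transient",
                           schedule = diurnal_schedule(0, 3,
                                                       lunar_modulation(29.530588,
                                                                        0.4)),
                           amplitude_jitter = 0.4, event_rate = 0.6,
                           level = 0.9),
    electrical = source_spec("electrical", band = c(1000, 5600),
                             kind = "tonal", peaks = c(1200, 3600, 5200),
                             schedule = constant_schedule(0.8),
                             amplitude_jitter = 0.5, event_rate = 0.9,
                             level = 0.6))
  scene_config(pool[sources], duration_days = duration_days, seed = seed,
               ...)
}
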