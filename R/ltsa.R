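#' Magnitude spectrogram of one audio clip
#'
#' Non-overlapping windowed DFT frames. With the conventional settings for
#' long-term monitoring (Hamming window, FFT size 4096, no overlap) a 30-s
#' clip at 384 kHz yields 2812 frames at 93.75 Hz frequency resolution; the
#' per-clip spectrogram is then collapsed to one LTSA column by
#' [mean_log_spectrum()].
#'
#' @param samples Mono waveform (numeric vector).
#' @param sample_rate Sampling rate in Hz.
#' @param fft_size Samples per frame (default 4096). The trailing partial
#'   frame is discarded.
#' @param window `"hamming"` (default), `"hann"` or `"rect"`.
#' @return A `clip_spectrogram`: list with `S` (magnitude, frequency bins x
#'   frames), `freq` (Hz, 0 to Nyquist) and `frames` (frame start times, s).
#' @export
clip_spectrogram <- function(samples, sample_rate, fft_size = 4096,
                             window = c("hamming", "hann", "rect")) {
  window <- match.arg(window)
  nfr <- floor(length(samples) / fft_size)
  if (nfr < 1)
    stop("clip shorter than one FFT frame (", length(samples), " < ",
         fft_size, " samples)")
  w <- switch(window,
              hamming = signal::hamming(fft_size),
              hann    = signal::hanning(fft_size),
              rect    = rep(1, fft_size))
  X <- matrix(samples[seq_len(nfr * fft_size)], fft_size, nfr) * w
  S <- Mod(stats::mvfft(X))[seq_len(fft_size / 2 + 1), , drop = FALSE]
  structure(list(S = S,
                 freq = (0:(fft_size / 2)) * sample_rate / fft_size,
                 frames = (seq_len(nfr) - 1) * fft_size / sample_rate),
            class = "clip_spectrogram")
}

#' Log-scaled mean spectrum of a clip spectrogram
#'
#' Averages the magnitude spectrogram over time and converts to decibels,
#' `10 * log10(mean(S(f, t)))`. This is one column of the LTSA. Bins whose
#' mean magnitude is zero are mapped to `floor_db` so the grid stays bounded;
#' prewhitening later zeroes them.
#'
#' @param spec A `clip_spectrogram` (or a nonnegative matrix, bins x frames).
#' @param floor_db Lower bound in dB for empty bins (default -120).
#' @return Numeric vector, one dB value per frequency bin (uncalibrated,
#'   relative).
#' @export
mean_log_spectrum <- function(spec, floor_db = -120) {
  S <- if (inherits(spec, "clip_spectrogram")) spec$S else spec
  if (!length(S)) stop("empty spectrogram")
  m <- rowMeans(S)
  p <- rep(floor_db, length(m))
  pos <- m > 0
  p[pos] <- pmax(10 * log10(m[pos]), floor_db)
  p
}

#' Build a long-term spectral average from audio clips
#'
#' Each fixed-duration clip contributes one column: the log-scaled mean of
#' its non-overlapping windowed magnitude spectrogram. Columns are ordered by
#' clip start time (parsed from the filename by default); missing clips leave
#' gaps in the time axis, which are kept as-is rather than filled.
#'
#' @param x A directory containing `.wav` clips, or a character vector of
#'   file paths.
#' @param fft_size FFT size in samples (default 4096).
#' @param fmax Keep only frequencies `<= fmax` Hz (default: Nyquist). Typical
#'   use caps the axis at the hydrophone's calibrated range.
#' @param window Analysis window, see [clip_spectrogram()].
#' @param time_parser Function mapping file paths to `POSIXct` start times;
#'   default [parse_clip_time()] (`YYYYMMDD_HHMMSS.wav`).
#' @param floor_db dB floor for empty bins, see [mean_log_spectrum()].
#' @return An `ltsa` object: list with `P` (dB grid, frequency x clips),
#'   `freq` (Hz), `time` (`POSIXct` clip starts), `clip_seconds`,
#'   `sample_rate` and `units`.
#' @export
build_ltsa <- function(x, fft_size = 4096, fmax = NULL,
                       window = "hamming", time_parser = parse_clip_time,
                       floor_db = -120) {
  files <- if (length(x) == 1 && dir.exists(x)) {
    list.files(x, pattern = "\\.[Ww][Aa][Vv]$", full.names = TRUE)
  } else as.character(x)
  if (!length(files)) stop("no audio clips found")
  times <- time_parser(files)
  ord <- order(times)
  files <- files[ord]
  times <- times[ord]
  sr <- NULL
  cols <- vector("list", length(files))
  freq <- NULL
  for (i in seq_along(files)) {
    wav <- read_wav(files[i])
    if (is.null(sr)) sr <- wav$sample_rate
    else if (wav$sample_rate != sr)
      stop("inconsistent sample rate in ", files[i], " (", wav$sample_rate,
           " Hz, expected ", sr, " Hz)")
    sp <- clip_spectrogram(wav$samples, sr, fft_size, window)
    if (is.null(freq)) freq <- sp$freq
    cols[[i]] <- mean_log_spectrum(sp, floor_db)
  }
  P <- do.call(cbind, cols)
  if (!is.null(fmax)) {
    keep <- freq <= fmax
    P <- P[keep, , drop = FALSE]
    freq <- freq[keep]
  }
  clip_sec <- length(read_wav(files[1])$samples) / sr
  structure(list(P = P, freq = freq, time = times,
                 clip_seconds = clip_sec, sample_rate = sr,
                 units = "dB (relative)"),
            class = "ltsa")
}

#' Assemble an LTSA object from an existing grid
#'
#' Convenience constructor for grids computed elsewhere (e.g. the synthetic
#' scene generator).
#'
#' @param P Numeric grid, frequency bins x clips.
#' @param freq Frequency axis (Hz), length `nrow(P)`.
#' @param time `POSIXct` clip start times, length `ncol(P)`.
#' @param clip_seconds Clip duration in seconds.
#' @param units Unit label.
#' @return An `ltsa` object.
#' @export
as_ltsa <- function(P, freq, time, clip_seconds = 30, units = "dB (relative)") {
  stopifnot(nrow(P) == length(freq), ncol(P) == length(time))
  structure(list(P = P, freq = freq, time = time,
                 clip_seconds = clip_seconds, sample_rate = NA_real_,
                 units = units),
            class = "ltsa")
}

#' Prewhiten an LTSA against a percentile noise floor
#'
#' Estimates the background as a low percentile (default the 10th) of each
#' frequency bin across time, subtracts it row-wise, and clips negative
#' values to zero. This equalizes the spectral gradient of ambient noise and
#' suppresses fixed-frequency interference, leaving signal-above-background.
#'
#' @param ltsa An `ltsa` object or a numeric grid (frequency x time).
#' @param percentile Noise-floor percentile as a fraction (default 0.10).
#'   Linear interpolation between order statistics is used.
#' @return A `prewhitened_ltsa`: list with the nonnegative grid `P`, the
#'   axes of the input, and `noise_floor` (dB per frequency bin).
#' @export
prewhiten <- function(ltsa, percentile = 0.10) {
  obj <- if (inherits(ltsa, "ltsa")) ltsa else
    list(P = ltsa, freq = seq_len(nrow(ltsa)), time = seq_len(ncol(ltsa)),
         clip_seconds = NA_real_, units = "dB (relative)")
  P <- obj$P
  if (ncol(P) < 10)
    stop("need at least 10 LTSA columns for a meaningful percentile (got ",
         ncol(P), ")")
  n10 <- apply(P, 1, stats::quantile, probs = percentile, names = FALSE,
               type = 7)
  Pw <- pmax(P - n10, 0)
  structure(list(P = Pw, freq = obj$freq, time = obj$time,
                 clip_seconds = obj$clip_seconds,
                 noise_floor = n10, percentile = percentile,
                 units = "dB above noise floor"),
            class = "prewhitened_ltsa")
}

#' @export
print.ltsa <- function(x, ...) {
  cat("LTSA: ", nrow(x$P), " frequency bins x ", ncol(x$P), " clips\n",
      sep = "")
  cat("  frequency: ", round(min(x$freq), 1), "-", round(max(x$freq), 1),
      " Hz\n", sep = "")
  if (inherits(x$time, "POSIXct"))
    cat("  time: ", format(min(x$time)), " to ", format(max(x$time)), "\n",
        sep = "")
  cat("  units: ", x$units, "\n", sep = "")
  invisible(x)
}

#' @export
print.prewhitened_ltsa <- function(x, ...) {
  cat("Prewhitened LTSA: ", nrow(x$P), " frequency bins x ", ncol(x$P),
      " clips\n", sep = "")
  if (is.finite(x$percentile))
    cat("  noise floor: ", signif(x$percentile * 100, 3),
        "th percentile per bin\n", sep = "")
  else cat("  noise floor: none (generated prewhitened)\n")
  cat("  zero fraction: ", round(mean(x$P == 0), 3), "\n", sep = "")
  invisible(x)
}

#' Heatmap of an LTSA grid
#'
#' @param x An `ltsa` or `prewhitened_ltsa`.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ltsa <- function(x, main = "LTSA", ...) {
  tx <- if (inherits(x$time, "POSIXct")) as.numeric(x$time) else x$time
  graphics::image(tx, x$freq, t(x$P), xlab = "time", ylab = "frequency (Hz)",
                  main = main, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' @export
plot.prewhitened_ltsa <- function(x, main = "Prewhitened LTSA", ...) {
  plot.ltsa(x, main = main, ...)
}

#' Persist / load an LTSA-like object
#'
#' Stores the grid, axes and metadata in a single-file archive (RDS).
#'
#' @param x An `ltsa`, `prewhitened_ltsa` or separated-source object.
#' @param path File path.
#' @return `path` (write) or the restored object (read).
#' @export
write_ltsa <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_ltsa
#' @export
read_ltsa <- function(path) readRDS(path)
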