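#' Relative intensity series of a separated channel
#'
#' Integrates a separated LTSA channel over frequency, zeroes any masked
#' (known-corrupt) time ranges, and min-max normalizes to `[0, 1]` using the
#' unmasked extremes, so the unmasked minimum maps to 0 and the maximum to 1.
#'
#' @param source_grid A per-source grid: matrix (frequency x time), or an
#'   element of [separate()]'s output together with `time`.
#' @param time `POSIXct` (or numeric) axis, one per column; taken from the
#'   object when available.
#' @param mask_ranges List of `c(start, end)` pairs (same scale as `time`)
#'   whose frames are forced to 0 before normalization.
#' @param source Label attached to the series.
#' @return An `intensity_series`: list with `time`, `value` (in `[0, 1]`),
#'   `masked` (logical) and `source`.
#' @export
intensity_series <- function(source_grid, time = NULL, mask_ranges = NULL,
                             source = "source") {
  P <- if (is.list(source_grid)) source_grid$P %||% source_grid[[1]]
       else source_grid
  if (any(P < 0)) stop("separated grids must be nonnegative")
  if (is.null(time)) {
    time <- if (is.list(source_grid) && !is.null(source_grid$time))
      source_grid$time else seq_len(ncol(P))
  }
  v <- colSums(P)
  masked <- rep(FALSE, length(v))
  for (rg in mask_ranges %||% list())
    masked <- masked | (time >= rg[1] & time <= rg[2])
  v[masked] <- 0
  un <- v[!masked]
  if (!length(un) || max(un) == min(un)) {
    warning("constant intensity series; returning all zeros")
    v[] <- 0
  } else {
    v <- (v - min(un)) / (max(un) - min(un))
    v[masked] <- 0
    v <- pmin(pmax(v, 0), 1)
  }
  structure(list(time = time, value = v, masked = masked, source = source),
            class = "intensity_series")
}

#' @export
print.intensity_series <- function(x, ...) {
  cat("Intensity series '", x$source, "': ", length(x$value), " frames",
      sep = "")
  if (any(x$masked)) cat(" (", sum(x$masked), " masked)", sep = "")
  cat("\n  active fraction (>= 0.05): ",
      round(mean(x$value >= 0.05), 3), "\n", sep = "")
  invisible(x)
}

#' Time-lagged correlation with sliding-window envelope
#'
#' Pearson correlation between two intensity series at every integer-frame
#' lag up to `max_lag` (autocorrelation when `b` is missing). Gaps (`NA`
#' values) are handled by pairwise-complete overlap; a lag is reported only
#' when at least `min_overlap` of the nominal overlap is available. The
#' envelope is a centered moving maximum (1-day window by default), the
#' convention used to read lunar and seasonal recurrence off a correlogram
#' dominated by the diurnal cycle; peaks are strict local maxima of the
#' envelope with a minimum prominence.
#'
#' @param a,b `intensity_series` on the same time grid (`b = a` for
#'   autocorrelation).
#' @param max_lag Maximum lag in seconds.
#' @param envelope_window Envelope window in seconds (default 1 day).
#' @param min_overlap Minimum fraction of nominal overlap for a lag to be
#'   scored (default 0.5).
#' @param prominence Minimum envelope peak prominence (default 0.01).
#' @return A `lag_correlation`: list with `lag` (seconds, `-max_lag` to
#'   `max_lag` for cross-correlation, `0` to `max_lag` for autocorrelation),
#'   `score`, `envelope`, `peaks` (data.frame `lag`, `score`) and
#'   `frame_seconds`.
#' @export
lag_correlation <- function(a, b = NULL, max_lag, envelope_window = 86400,
                            min_overlap = 0.5, prominence = 0.01) {
  stopifnot(inherits(a, "intensity_series"))
  auto <- is.null(b)
  if (auto) b <- a
  stopifnot(inherits(b, "intensity_series"))
  if (length(a$value) != length(b$value))
    stop("series must share a common time grid")
  dt <- if (length(a$time) > 1) as.numeric(difftime(a$time[2], a$time[1],
                                                    units = "secs")) else 1
  if (!is.finite(dt) || dt <= 0) dt <- 1
  x <- a$value; y <- b$value
  n <- length(x)
  L <- min(floor(max_lag / dt), n - 2)
  lag_frames <- if (auto) 0:L else (-L):L
  score <- rep(NA_real_, length(lag_frames))
  for (i in seq_along(lag_frames)) {
    k <- lag_frames[i]
    if (k >= 0) { xi <- x[seq_len(n - k)]; yi <- y[seq.int(1 + k, n)] }
    else       { xi <- x[seq.int(1 - k, n)]; yi <- y[seq_len(n + k)] }
    ok <- !is.na(xi) & !is.na(yi)
    if (sum(ok) < min_overlap * length(xi) || sum(ok) < 3) next
    s <- suppressWarnings(stats::cor(xi[ok], yi[ok]))
    score[i] <- s
  }
  wk <- max(1, round(envelope_window / dt))
  if (wk %% 2 == 0) wk <- wk + 1
  env <- if (wk >= 3 && length(score) >= wk) {
    zoo::rollapply(zoo::zoo(score), wk, function(z) {
      if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)
    }, fill = NA, align = "center")
  } else score
  env <- as.numeric(env)
  pk <- .find_peaks(env, prominence)
  structure(list(lag = lag_frames * dt, score = score, envelope = env,
                 peaks = data.frame(lag = lag_frames[pk] * dt,
                                    score = env[pk]),
                 frame_seconds = dt, auto = auto),
            class = "lag_correlation")
}

#' @export
print.lag_correlation <- function(x, ...) {
  cat(if (x$auto) "Autocorrelation" else "Cross-correlation",
      ": lags up to ", round(max(abs(x$lag)) / 86400, 2), " days (frame ",
      x$frame_seconds, " s)\n", sep = "")
  if (nrow(x$peaks)) {
    top <- x$peaks[order(-x$peaks$score), , drop = FALSE]
    top <- utils::head(top[top$lag > 0, , drop = FALSE], 5)
    cat("  leading envelope peaks (days): ",
        paste(sprintf("%.2f (r=%.2f)", top$lag / 86400, top$score),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.lag_correlation <- function(x, ...) {
  d <- x$lag / 86400
  graphics::plot(d, x$score, type = "l", col = "grey50",
                 xlab = "lag (days)", ylab = "correlation", ...)
  graphics::lines(d, x$envelope, col = "blue")
  if (nrow(x$peaks))
    graphics::points(x$peaks$lag / 86400, x$peaks$score, pch = 1,
                     col = "red")
  invisible(x)
}

#' Cycle model of relative intensity (diurnal, lunar or seasonal)
#'
#' Folds the series on the chosen cycle, pools values into bins (10-min
#' time-of-day bins for the diurnal cycle; daily-scale bins folded on the
#' 29.53-day synodic period or the calendar year otherwise), summarizes each
#' bin by its 95th percentile (plus mean and SD), and interpolates the
#' percentile profile with a periodic cubic spline.
#'
#' @param series An `intensity_series` with a `POSIXct` time axis.
#' @param kind `"diurnal"`, `"lunar"` or `"seasonal"`.
#' @param probs Percentile summarized per bin (default 0.95).
#' @param lunar_epoch Reference new moon anchoring the lunar fold.
#' @param synodic_days Synodic month length (default 29.530588).
#' @param include_masked Masked frames are dropped by default.
#' @return A `cycle_model`: list with `kind`, `cycle_hours`, bin `centers`
#'   (hours for diurnal, days otherwise), `q`, `mean`, `sd`, `n`, a periodic
#'   spline evaluator `fun(phase)`, and `peak` (phase of the spline
#'   maximum).
#' @export
cycle_model <- function(series, kind = c("diurnal", "lunar", "seasonal"),
                        probs = 0.95,
                        lunar_epoch = as.POSIXct("2000-01-06 18:14:00",
                                                 tz = "UTC"),
                        synodic_days = 29.530588, include_masked = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(series, "intensity_series"))
  t <- series$time
  v <- series$value
  if (!include_masked) { t <- t[!series$masked]; v <- v[!series$masked] }
  if (!length(t)) stop("no unmasked values to model")
  dt_days <- if (length(t) > 1)
    stats::median(as.numeric(diff(t), units = "days")) else 0
  span_days <- as.numeric(difftime(max(t), min(t), units = "days")) +
    dt_days                                    # frames cover [t, t + dt)
  cyc_days <- switch(kind, diurnal = 1, lunar = synodic_days,
                     seasonal = 365.25)
  if (span_days < 2 * cyc_days)
    stop("series spans ", round(span_days, 2), " days; need at least 2 ",
         kind, " cycles (", round(2 * cyc_days, 1), " days)")
  phase <- switch(kind,
    diurnal = (as.numeric(t) %% 86400) / 3600,                     # hours
    lunar = (as.numeric(difftime(t, lunar_epoch, units = "days")) %%
               synodic_days),                                      # days
    seasonal = as.numeric(difftime(
      t, as.POSIXct(paste0(format(t, "%Y"), "-01-01"), tz = "UTC"),
      units = "days")))                                            # days
  nbins <- switch(kind, diurnal = 144, lunar = 30, seasonal = 366)
  cycle_len <- switch(kind, diurnal = 24, lunar = synodic_days,
                      seasonal = 366)
  edges <- seq(0, cycle_len, length.out = nbins + 1)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  bin <- pmin(findInterval(phase, edges, rightmost.closed = TRUE), nbins)
  qv <- mv <- sv <- rep(NA_real_, nbins)
  nn <- integer(nbins)
  for (i in seq_len(nbins)) {
    z <- v[bin == i]
    nn[i] <- length(z)
    if (length(z)) {
      qv[i] <- stats::quantile(z, probs, names = FALSE, type = 7)
      mv[i] <- mean(z)
      sv[i] <- if (length(z) > 1) stats::sd(z) else 0
    }
  }
  ok <- which(!is.na(qv))
  if (length(ok) < 4) stop("too few populated bins for a spline fit")
  fx <- centers[ok]
  fy <- qv[ok]
  fun <- stats::splinefun(c(fx, fx[1] + cycle_len), c(fy, fy[1]),
                          method = "periodic")
  eval_fun <- function(phase) fun(phase %% cycle_len)
  grid <- seq(0, cycle_len, length.out = 2000)
  peak <- grid[which.max(eval_fun(grid))]
  structure(list(kind = kind, cycle_hours = cycle_len *
                   if (kind == "diurnal") 1 else 24,
                 centers = centers, q = qv, mean = mv, sd = sv, n = nn,
                 probs = probs, fun = eval_fun, peak = peak,
                 source = series$source),
            class = "cycle_model")
}

#' @export
print.cycle_model <- function(x, ...) {
  unit <- if (x$kind == "diurnal") "h" else "d"
  cat("Cycle model (", x$kind, ") for '", x$source, "'\n", sep = "")
  cat("  bins: ", sum(x$n > 0), "/", length(x$centers), " populated; ",
      "statistic: ", x$probs * 100, "th percentile\n", sep = "")
  cat("  peak phase: ", round(x$peak, 2), " ", unit, "\n", sep = "")
  if (x$kind == "seasonal")
    cat("  peak week: ", ceiling((x$peak + 1e-9) / 7), "\n", sep = "")
  invisible(x)
}

#' @export
plot.cycle_model <- function(x, ...) {
  unit <- if (x$kind == "diurnal") "hour" else "day of cycle"
  graphics::plot(x$centers, x$q, pch = 16, cex = 0.5, xlab = unit,
                 ylab = "relative intensity", ylim = c(0, 1), ...)
  grid <- seq(0, max(x$centers), length.out = 500)
  graphics::lines(grid, x$fun(grid), lwd = 2)
  lo <- pmax(x$mean - x$sd, 0); hi <- pmin(x$mean + x$sd, 1)
  ok <- !is.na(lo)
  graphics::polygon(c(x$centers[ok], rev(x$centers[ok])),
                    c(lo[ok], rev(hi[ok])),
                    col = grDevices::adjustcolor("grey", 0.4), border = NA)
  invisible(x)
}
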