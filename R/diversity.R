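#' Detect acoustic events in an intensity series
#'
#' Frames at or above `threshold` are detections. Consecutive detections
#' separated by a gap of at most `merge_gap` belong to one event (a gap
#' must exceed 10 min to split, by default); events shorter than
#' `min_duration` are discarded. Each event's mean spectrum is the
#' arithmetic mean over its detected frames in the separated grid, then
#' min-max normalized.
#'
#' @param series An `intensity_series`.
#' @param source_grid The matching separated grid (matrix frequency x time,
#'   or a list with `P`); needed for event spectra. May be `NULL` if only
#'   event times are wanted.
#' @param threshold Detection threshold on relative intensity, in (0, 1)
#'   (default 0.05).
#' @param merge_gap Maximum merging gap in seconds (default 600).
#' @param min_duration Minimum event duration in seconds (default 60).
#' @return An `acoustic_events` object: data.frame with `event`, `start`,
#'   `end`, `duration_min`, `n_frames`; attributes `spectra` (events x
#'   frequency, normalized), `frames` (list of detected frame indices),
#'   `time`, `freq`, `frame_seconds`, `source`.
#' @export
detect_events <- function(series, source_grid = NULL, threshold = 0.05,
                          merge_gap = 600, min_duration = 60) {
  stopifnot(inherits(series, "intensity_series"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  t <- series$time
  dt <- if (length(t) > 1) as.numeric(difftime(t[2], t[1], units = "secs"))
        else 30
  det <- which(series$value >= threshold)
  P <- if (is.list(source_grid)) source_grid$P else source_grid
  freq <- if (is.list(source_grid)) source_grid$freq else NULL
  empty <- function() {
    ev <- data.frame(event = integer(0), start = t[0], end = t[0],
                     duration_min = numeric(0), n_frames = integer(0))
    structure(ev, spectra = matrix(0, 0, if (is.null(P)) 0 else nrow(P)),
              frames = list(), time = t, freq = freq, frame_seconds = dt,
              source = series$source, class = c("acoustic_events",
                                                "data.frame"))
  }
  if (!length(det)) return(empty())
  ## group detections: a new event starts when the silent gap between the
  ## end of the previous detection frame and the start of the next exceeds
  ## merge_gap
  gaps <- (det[-1] - det[-length(det)] - 1) * dt
  grp <- cumsum(c(1, gaps > merge_gap))
  frames <- split(det, grp)
  dur <- vapply(frames, function(ix) {
    (max(ix) - min(ix) + 1) * dt           # span incl. merged short gaps
  }, numeric(1))
  keep <- dur >= min_duration
  frames <- frames[keep]
  if (!length(frames)) return(empty())
  dur <- dur[keep]
  starts <- t[vapply(frames, min, integer(1))]
  ends <- t[vapply(frames, max, integer(1))] + dt
  nf <- if (is.null(P)) 0L else nrow(P)
  spectra <- matrix(0, length(frames), nf)
  if (!is.null(P)) {
    for (i in seq_along(frames)) {
      ms <- rowMeans(P[, frames[[i]], drop = FALSE])
      rg <- range(ms)
      spectra[i, ] <- if (rg[2] > rg[1]) (ms - rg[1]) / (rg[2] - rg[1])
                      else 0
    }
  }
  ev <- data.frame(event = seq_along(frames), start = starts, end = ends,
                   duration_min = dur / 60,
                   n_frames = vapply(frames, length, integer(1)))
  structure(ev, spectra = spectra, frames = unname(frames), time = t,
            freq = freq, frame_seconds = dt, source = series$source,
            class = c("acoustic_events", "data.frame"))
}

#' @export
print.acoustic_events <- function(x, ...) {
  cat("Acoustic events for '", attr(x, "source"), "': ", nrow(x),
      " events\n", sep = "")
  if (nrow(x))
    cat("  total duration: ", round(sum(x$duration_min), 1),
        " min; median ", round(stats::median(x$duration_min), 1),
        " min\n", sep = "")
  NextMethod()
}

#' Cluster acoustic events by their mean spectra
#'
#' PCA reduces the normalized event spectra to the smallest number of
#' components explaining more than `pca_variance` of the variance; k-means
#' (best of `nstart` seeded restarts) is run in that space for every `k` in
#' `k_range`. Each solution is scored by the percentage of total dispersion
#' it represents,
#' \deqn{R_k = 100 (1 - \sum_i D_i / D_1),}
#' where `D_i` is the within-cluster sum of squared distances to the
#' centroid and `D_1` the total sum of squares around the global centroid.
#'
#' @param events An `acoustic_events` object (or a plain matrix of event
#'   spectra, events x frequency).
#' @param k_range Integer vector of cluster counts to try.
#' @param pca_variance Fraction of variance the kept components must exceed
#'   (default 0.90).
#' @param seed Integer seed (each `k` uses a derived seed).
#' @param nstart k-means restarts per `k` (default 10).
#' @return A `cluster_scan`: list with `results` (per `k`: `k`, `cluster`
#'   assignments, `centers`, `D_i`, `D1`, `R`), `r_curve` (data.frame `k`,
#'   `R`), `pca` (`n_components`, `variance_explained`, rotation, center),
#'   `scores` (PCA coordinates).
#' @export
cluster_events <- function(events, k_range = 2:10, pca_variance = 0.90,
                           seed = 1, nstart = 10) {
  X <- if (is.matrix(events)) events else attr(events, "spectra")
  if (is.null(X) || !nrow(X)) stop("no event spectra to cluster")
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(X))
    stop("k (", max(k_range), ") exceeds the number of events (", nrow(X),
         ")")
  keep_col <- apply(X, 2, function(z) stats::sd(z) > 0)
  if (sum(keep_col) < 2) {
    warning("event spectra are (near) identical; dispersion undefined")
    keep_col <- rep(TRUE, ncol(X))
  }
  pca <- stats::prcomp(X[, keep_col, drop = FALSE], center = TRUE,
                       scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  ncomp <- which(cum > pca_variance)[1]
  if (is.na(ncomp)) ncomp <- length(cum)
  Y <- pca$x[, seq_len(ncomp), drop = FALSE]
  D1 <- sum(scale(Y, scale = FALSE)^2)
  results <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- .with_seed(seed + k, {
      if (k == 1) {
        ctr <- matrix(colMeans(Y), 1)
        list(cluster = rep(1L, nrow(Y)), centers = ctr,
             withinss = D1)
      } else if (k == nrow(Y)) {
        list(cluster = seq_len(nrow(Y)), centers = Y,
             withinss = rep(0, nrow(Y)))
      } else {
        km <- stats::kmeans(Y, centers = k, nstart = nstart, iter.max = 100)
        list(cluster = km$cluster, centers = km$centers,
             withinss = km$withinss)
      }
    })
    R <- if (D1 > 0) 100 * (1 - sum(fit$withinss) / D1) else NA_real_
    results[[i]] <- list(k = k, cluster = fit$cluster,
                         centers = fit$centers, D_i = fit$withinss,
                         D1 = D1, R = R)
  }
  structure(list(results = results,
                 r_curve = data.frame(
                   k = k_range,
                   R = vapply(results, `[[`, numeric(1), "R")),
                 pca = list(n_components = ncomp,
                            variance_explained = cum[ncomp],
                            rotation = pca$rotation[, seq_len(ncomp),
                                                    drop = FALSE],
                            center = pca$center, columns = keep_col),
                 scores = Y, k_range = k_range),
            class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat("Cluster scan over k = ", min(x$k_range), "..", max(x$k_range),
      " (PCA: ", x$pca$n_components, " components, ",
      round(100 * x$pca$variance_explained, 2), "% variance)\n", sep = "")
  print(x$r_curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cluster_scan <- function(x, ...) {
  graphics::plot(x$r_curve$k, x$r_curve$R, type = "b", xlab = "k",
                 ylab = expression(R[k] ~ "(%)"), ylim = c(0, 100), ...)
  invisible(x)
}

#' Choose the number of clusters from an R-vs-k curve
#'
#' Returns the smallest `k` whose dispersion score reaches `r_threshold`.
#' When no `k` reaches it, the elbow of the curve (the interior `k` with the
#' most negative discrete second difference) is returned with a warning.
#'
#' @param scan A `cluster_scan` (or data.frame with `k` and `R`).
#' @param r_threshold Required percentage of dispersion (default 93).
#' @return Chosen `k` (integer) with attribute `rule` (`"threshold"` or
#'   `"elbow"`).
#' @export
choose_k <- function(scan, r_threshold = 93) {
  curve <- if (inherits(scan, "cluster_scan")) scan$r_curve else
    as.data.frame(scan)
  if (!nrow(curve)) stop("empty cluster scan")
  ok <- which(curve$R >= r_threshold)
  if (length(ok))
    return(structure(curve$k[ok[1]], rule = "threshold"))
  if (nrow(curve) < 3) {
    warning("R never reaches ", r_threshold,
            "% and the curve is too short for an elbow; returning max k")
    return(structure(curve$k[nrow(curve)], rule = "elbow"))
  }
  d2 <- diff(curve$R, differences = 2)
  k_elbow <- curve$k[which.min(d2) + 1]
  warning("R never reaches ", r_threshold, "%; returning elbow k = ",
          k_elbow)
  structure(k_elbow, rule = "elbow")
}

#' Per-cluster spectra and temporal detection probabilities
#'
#' For every cluster: the duration-weighted mean of member spectra, and
#' hourly (24) and monthly (12) detection-probability vectors computed by
#' dividing the detected duration in each time category by the cluster's
#' total detected duration (each vector sums to 1).
#'
#' @param events An `acoustic_events` object.
#' @param result One element of a [cluster_events()] scan (a list with
#'   `cluster`), or the `cluster_scan` plus `k`.
#' @param k When `result` is a `cluster_scan`, the `k` to summarize.
#' @return A `cluster_summary`: list per cluster with `mean_spectrum`,
#'   `hourly` (24 probabilities), `monthly` (12 probabilities),
#'   `n_events`, `total_min`.
#' @export
summarize_clusters <- function(events, result, k = NULL) {
  if (inherits(result, "cluster_scan")) {
    stopifnot(!is.null(k))
    result <- result$results[[match(k, result$k_range)]]
  }
  cl <- result$cluster
  stopifnot(length(cl) == nrow(events))
  spectra <- attr(events, "spectra")
  frames <- attr(events, "frames")
  tax <- attr(events, "time")
  dt_min <- attr(events, "frame_seconds") / 60
  out <- vector("list", max(cl))
  for (g in seq_len(max(cl))) {
    ix <- which(cl == g)
    if (!length(ix)) {
      warning("cluster ", g, " is empty")
      out[[g]] <- list(mean_spectrum = numeric(ncol(spectra)),
                       hourly = numeric(24), monthly = numeric(12),
                       n_events = 0L, total_min = 0)
      next
    }
    wts <- events$duration_min[ix]
    msp <- colSums(spectra[ix, , drop = FALSE] * wts) / sum(wts)
    ft <- tax[unlist(frames[ix])]
    hours <- as.integer(format(ft, "%H"))
    months <- as.integer(format(ft, "%m"))
    hourly <- vapply(0:23, function(h) sum(hours == h) * dt_min, numeric(1))
    monthly <- vapply(1:12, function(m) sum(months == m) * dt_min,
                      numeric(1))
    out[[g]] <- list(mean_spectrum = msp,
                     hourly = hourly / sum(hourly),
                     monthly = monthly / sum(monthly),
                     n_events = length(ix),
                     total_min = sum(events$duration_min[ix]))
  }
  structure(list(clusters = out, k = max(cl), source = attr(events,
                                                            "source")),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat("Cluster summary for '", x$source, "': ", x$k, " clusters\n",
      sep = "")
  for (g in seq_along(x$clusters)) {
    cli <- x$clusters[[g]]
    ph <- if (sum(cli$hourly) > 0) which.max(cli$hourly) - 1 else NA
    cat("  cluster ", g, ": ", cli$n_events, " events, ",
        round(cli$total_min, 1), " min, peak hour ", ph, "\n", sep = "")
  }
  invisible(x)
}

#' Export an events table to CSV
#'
#' @param events An `acoustic_events` object.
#' @param path Output CSV path.
#' @param cluster Optional cluster assignments to include.
#' @export
write_events_csv <- function(events, path, cluster = NULL) {
  df <- data.frame(source = attr(events, "source"),
                   start_iso = format(events$start, "%Y-%m-%dT%H:%M:%SZ"),
                   end_iso = format(events$end, "%Y-%m-%dT%H:%M:%SZ"),
                   duration_min = events$duration_min)
  if (!is.null(cluster)) df$cluster_id <- cluster
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
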