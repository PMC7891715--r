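# shared in-code fixtures

# tiny two-source scene with disjoint bands and distinct periods
tiny_two_source_scene <- function(duration_days = 4, seed = 7) {
  lo <- source_spec("low", band = c(200, 1500), kind = "chorus",
                    schedule = diurnal_schedule(20, 1.5),
                    amplitude_jitter = 0.1, event_rate = 1)
  hi <- source_spec("high", band = c(4000, 7500), kind = "transient",
                    schedule = diurnal_schedule(8, 3,
                                                lunar_modulation(2, 0.2)),
                    amplitude_jitter = 0.1, event_rate = 1)
  scene_config(list(lo, hi), duration_days = duration_days, n_freq = 40,
               seed = seed)
}

# deterministic intensity series on a 30-s grid
make_series <- function(values, start = as.POSIXct("2012-06-01 00:00:00",
                                                   tz = "UTC"),
                        dt = 30, source = "toy") {
  structure(list(time = start + (seq_along(values) - 1) * dt,
                 value = values, masked = rep(FALSE, length(values)),
                 source = source),
            class = "intensity_series")
}

# brute-force closed-form oracle for the sparseness projection: enumerate
# supports; on each support the feasible set {sum = l1, ||.|| = l2, v >= 0}
# is a sphere-slice whose closest point to x is computed analytically
oracle_project <- function(x, target) {
  n <- length(x)
  l2 <- sqrt(sum(x^2))
  l1 <- l2 * (sqrt(n) - target * (sqrt(n) - 1))
  best <- NULL
  bestd <- Inf
  for (sz in n:1) {
    for (sel in utils::combn(n, sz, simplify = FALSE)) {
      k <- length(sel)
      r2 <- l2^2 - l1^2 / k
      if (r2 < -1e-12) next
      r <- sqrt(max(r2, 0))
      m <- rep(l1 / k, k)
      xs <- x[sel]
      w <- xs - sum(xs) / k   # in-hyperplane component of xs about the center
      nw <- sqrt(sum(w^2))
      v <- if (nw < 1e-14 || r == 0) m else m + w / nw * r
      if (any(v < -1e-10)) next
      full <- numeric(n)
      full[sel] <- pmax(v, 0)
      d <- sum((full - x)^2)
      if (d < bestd - 1e-12) { bestd <- d; best <- full }
    }
  }
  list(v = best, dist2 = bestd)
}

# three well-separated groups of synthetic event spectra
make_grouped_spectra <- function(n_per = 20, p = 30, sd = 0.02, seed = 21) {
  set.seed(seed)
  centers <- list(stats::dnorm(1:p, 6, 2), stats::dnorm(1:p, 15, 2),
                  stats::dnorm(1:p, 24, 2))
  X <- do.call(rbind, lapply(centers, function(ctr) {
    t(replicate(n_per, ctr / max(ctr) + stats::rnorm(p, 0, sd)))
  }))
  list(X = pmax(X, 0), labels = rep(1:3, each = n_per))
}

# brute-force event detection oracle: scan frames, apply threshold, the
# strict >gap split and the <min duration discard literally
oracle_events <- function(values, dt, threshold, merge_gap, min_duration) {
  det <- which(values >= threshold)
  if (!length(det)) return(list())
  groups <- list(det[1])
  for (i in det[-1]) {
    last <- groups[[length(groups)]]
    gap <- (i - last[length(last)] - 1) * dt
    if (gap > merge_gap) groups[[length(groups) + 1]] <- i
    else groups[[length(groups)]] <- c(last, i)
  }
  keep <- vapply(groups, function(g)
    (g[length(g)] - g[1] + 1) * dt >= min_duration, logical(1))
  groups[keep]
}
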