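#' Fold an LTSA into fixed-length time patches
#'
#' Consecutive groups of `frames_per_patch` columns are vectorized
#' (frequency-major within each frame, frames concatenated) into single
#' columns, so each learned spectral feature can span a longer time context
#' (15 min with 30-s clips and the default of 30 frames). The final partial
#' patch is zero-padded; [unfold()] discards the padding.
#'
#' @param grid A `prewhitened_ltsa` or nonnegative matrix (frequency x time).
#' @param frames_per_patch Number of consecutive frames per patch (B >= 1).
#' @return A `folded_ltsa`: list with `V` ((frequency * B) x patches),
#'   `n_freq`, `n_time`, `frames_per_patch`.
#' @export
fold <- function(grid, frames_per_patch) {
  P <- if (inherits(grid, "prewhitened_ltsa") || inherits(grid, "ltsa"))
    grid$P else grid
  B <- as.integer(frames_per_patch)
  if (B < 1) stop("frames_per_patch must be >= 1")
  nf <- nrow(P); nt <- ncol(P)
  m <- ceiling(nt / B)
  pad <- m * B - nt
  if (pad > 0) P <- cbind(P, matrix(0, nf, pad))
  structure(list(V = matrix(P, nf * B, m), n_freq = nf, n_time = nt,
                 frames_per_patch = B),
            class = "folded_ltsa")
}

#' @rdname fold
#' @param folded A `folded_ltsa`, or a matrix together with `n_freq` and
#'   `n_time`.
#' @param n_freq,n_time Original grid extent (taken from `folded` when it is
#'   a `folded_ltsa`).
#' @return `unfold()`: the original frequency x time matrix.
#' @export
unfold <- function(folded, n_freq = NULL, n_time = NULL) {
  if (inherits(folded, "folded_ltsa")) {
    V <- folded$V; n_freq <- folded$n_freq; n_time <- folded$n_time
  } else V <- folded
  G <- matrix(V, nrow = n_freq)
  G[, seq_len(n_time), drop = FALSE]
}

## 0.5 * squared Frobenius reconstruction error
.nmf_obj <- function(V, W, H) 0.5 * sum((V - W %*% H)^2)

## the same objective through its Gram expansion: with HHt = H H', VHt =
## V H', normV2 = sum(V^2), cost(W) = (normV2 - 2 tr(W'VHt) + tr(W HHt W'))/2.
## Line-search candidates then cost O(d r^2) instead of O(d r m).
.nmf_obj_gram <- function(W, HHt, VHt, normV2) {
  0.5 * (normV2 - 2 * sum(W * VHt) + sum((W %*% HHt) * W))
}

## multiplicative Euclidean update of H (monotone for fixed W); WtV and WtW
## are precomputed so repeated calls cost O(r^2 m)
.update_h <- function(WtV, WtW, H, eps = 1e-16) {
  H * (WtV / (WtW %*% H + eps))
}

## projected gradient step on W with backtracking; every column is projected
## back onto the target sparseness set (L2 norm of the stepped column kept)
.update_w_sparse <- function(HHt, VHt, normV2, W, target, mu, obj_prev) {
  grad <- W %*% HHt - VHt
  for (try in 1:40) {
    Wn <- W - mu * grad
    for (j in seq_len(ncol(Wn))) {
      cj <- Wn[, j]
      l2 <- sqrt(sum(cj^2))
      if (!is.finite(l2) || l2 < 1e-12) {
        Wn[, j] <- W[, j]           # degenerate step: keep previous feature
        next
      }
      Wn[, j] <- .project_l1l2(cj, l2 * (sqrt(length(cj)) -
                                         target * (sqrt(length(cj)) - 1)), l2)
    }
    obj <- .nmf_obj_gram(Wn, HHt, VHt, normV2)
    if (obj <= obj_prev) return(list(W = Wn, mu = mu * 1.2, obj = obj))
    mu <- mu / 2
  }
  list(W = W, mu = mu, obj = obj_prev)  # no descent step found: keep W
}

## plain multiplicative Euclidean NMF (layer 2); returns factors + objective
.nmf_plain <- function(V, rank, iterations, eps = 1e-16) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * rank), n, rank)
  H <- matrix(stats::runif(rank * m), rank, m)
  obj <- numeric(iterations)
  for (it in seq_len(iterations)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * ((V %*% t(H)) / (W %*% tcrossprod(H) + eps))
    obj[it] <- .nmf_obj(V, W, H)
  }
  list(W = W, H = H, objective = obj)
}

## activation rows -> periodicity vectors: magnitude DFT, DC removed,
## unit-sum normalized per feature (scale-free recurrence signature)
.periodicity_matrix <- function(H) {
  m <- ncol(H)
  nb <- floor(m / 2)
  Q <- matrix(0, nb, nrow(H))
  for (a in seq_len(nrow(H))) {
    q <- Mod(stats::fft(H[a, ]))[2:(nb + 1)]
    s <- sum(q)
    Q[, a] <- if (s > 0) q / s else rep(1 / nb, nb)
  }
  Q
}

#' Fit a periodicity-coded NMF source separation model
#'
#' Two-layer blind source separation for long-term spectral averages. The
#' first layer factorizes the (folded) prewhitened LTSA into nonnegative
#' spectral features `W` and temporal activations `H`, with every feature
#' constrained to a fixed Hoyer sparseness; `W` is updated by projected
#' gradient descent with backtracking (so the objective never increases) and
#' `H` by multiplicative Euclidean updates. Each feature's activation row is
#' then converted to a periodicity vector (magnitude DFT, DC removed,
#' normalized), and the second layer factorizes the periodicity matrix into
#' `n_sources` periodicity features and per-feature source indicators.
#' Features are assigned to the source with the largest indicator (ties to
#' the lowest source index); assignments can be revised with
#' [adjust_indicators()].
#'
#' @param x A `prewhitened_ltsa`, `folded_ltsa`, or nonnegative matrix
#'   (frequency x time).
#' @param n_features Number of spectral features to learn (default 90).
#' @param n_sources Number of sources for the periodicity layer (default 4).
#' @param frames_per_patch Frames folded into each patch (default 30, i.e.
#'   15 min of 30-s clips); ignored when `x` is already folded.
#' @param sparseness_target Hoyer sparseness of each feature (default 0.5:
#'   roughly half the elements of each feature active).
#' @param iterations Layer-1 training iterations (default 200).
#' @param layer2_iterations Iterations for the periodicity factorization
#'   (default 500).
#' @param seed Integer seed; fixes the random initialization of both layers.
#' @return A `pcnmf` object with elements `W` (features, columns
#'   L2-normalized), `H` (training activations), `Q` (periodicity matrix),
#'   `Wp`/`Hs` (periodicity features and source indicators), `assignment`
#'   (per-feature source), `overrides` (empty), `objective` /
#'   `objective_layer2` (per-iteration traces), and `config`.
#' @seealso [predict.pcnmf()], [separate()], [adjust_indicators()]
#' @export
pcnmf <- function(x, n_features = 90, n_sources = 4, frames_per_patch = 30,
                  sparseness_target = 0.5, iterations = 200,
                  layer2_iterations = 500, seed = 1) {
  folded <- if (inherits(x, "folded_ltsa")) x else fold(x, frames_per_patch)
  V <- folded$V
  if (!all(is.finite(V))) stop("non-finite values in the input grid")
  if (any(V < 0)) stop("input grid must be nonnegative (prewhitened)")
  if (max(V) == 0) stop("input grid is all zero")
  if (n_features >= min(dim(V)))
    warning("n_features (", n_features, ") >= min input dimension (",
            min(dim(V)), "); the factorization is overcomplete")
  d <- nrow(V); m <- ncol(V)

  .with_seed(seed, {
    W <- matrix(stats::runif(d * n_features), d, n_features)
    for (j in seq_len(n_features)) W[, j] <- project_sparseness(W[, j],
                                                                sparseness_target)
    H <- matrix(stats::runif(n_features * m), n_features, m)
    WH <- W %*% H
    H <- H * sum(V * WH) / max(sum(WH^2), 1e-300)  # optimal global scale
    obj <- numeric(iterations)
    mu <- 1 / max(colSums(H^2))
    normV2 <- sum(V^2)
    for (it in seq_len(iterations)) {
      WtV <- crossprod(W, V)
      H <- .update_h(WtV, crossprod(W), H)
      HHt <- tcrossprod(H)
      VHt <- tcrossprod(V, H)
      prev <- .nmf_obj_gram(W, HHt, VHt, normV2)
      st <- .update_w_sparse(HHt, VHt, normV2, W, sparseness_target, mu,
                             prev)
      W <- st$W; mu <- st$mu
      obj[it] <- st$obj
    }
    ## comparable indicator magnitudes: unit-L2 features, scale into H
    nrm <- sqrt(colSums(W^2))
    nrm[nrm == 0] <- 1
    W <- sweep(W, 2, nrm, "/")
    H <- H * nrm
    Q <- .periodicity_matrix(H)
    l2 <- .nmf_plain(Q, n_sources, layer2_iterations)
    assignment <- apply(l2$H, 2, which.max)   # ties: lowest source index
    structure(list(W = W, H = H, Q = Q, Wp = l2$W, Hs = l2$H,
                   assignment = as.integer(assignment),
                   overrides = integer(0),
                   objective = obj, objective_layer2 = l2$objective,
                   n_freq = folded$n_freq,
                   config = list(n_features = n_features,
                                 n_sources = n_sources,
                                 frames_per_patch = folded$frames_per_patch,
                                 sparseness_target = sparseness_target,
                                 iterations = iterations,
                                 layer2_iterations = layer2_iterations,
                                 seed = seed)),
              class = "pcnmf")
  })
}

#' Effective per-feature source assignment (manual overrides applied)
#'
#' @param model A `pcnmf` model.
#' @return Integer vector, one source id per spectral feature.
#' @export
source_assignment <- function(model) {
  a <- model$assignment
  if (length(model$overrides))
    a[as.integer(names(model$overrides))] <- as.integer(model$overrides)
  a
}

#' Manually adjust source indicators
#'
#' The periodicity layer occasionally groups a spectral feature with the
#' wrong source (e.g. a chorus feature assigned to a noise source when
#' periodicities are similar). Overrides reassign named features; the
#' original data-driven assignment is retained for audit and reported by
#' [summary.pcnmf()].
#'
#' @param model A `pcnmf` model.
#' @param overrides Named integer vector or list: names are feature ids,
#'   values are source ids (e.g. `c("7" = 2)`).
#' @return A new `pcnmf` model with the overrides recorded.
#' @export
adjust_indicators <- function(model, overrides) {
  stopifnot(inherits(model, "pcnmf"))
  if (!length(overrides)) return(model)
  ov <- unlist(overrides)
  feat <- suppressWarnings(as.integer(names(ov)))
  src <- as.integer(ov)
  nf <- model$config$n_features
  ns <- model$config$n_sources
  if (anyNA(feat) || any(feat < 1 | feat > nf))
    stop("unknown feature id in overrides (valid: 1..", nf, ")")
  if (anyNA(src) || any(src < 1 | src > ns))
    stop("unknown source id in overrides (valid: 1..", ns, ")")
  merged <- model$overrides
  merged[as.character(feat)] <- src
  model$overrides <- merged
  model
}

#' Predict activations of fixed spectral features
#'
#' The prediction phase: the learned dictionary `W` is held fixed and only
#' the activations are estimated for new data, by seeded random
#' initialization and multiplicative Euclidean updates (200 iterations by
#' default). The objective is non-increasing across iterations.
#'
#' @param object A `pcnmf` model.
#' @param newdata A `prewhitened_ltsa`, `folded_ltsa`, or matrix with the
#'   same frequency extent as the training data.
#' @param iterations Update iterations (default 200).
#' @param seed Integer seed for the activation initialization.
#' @param ... Unused.
#' @return A `pcnmf_activations` object: list with `H` (features x patches),
#'   `objective`, and the fold geometry.
#' @export
predict.pcnmf <- function(object, newdata, iterations = 200, seed = 1, ...) {
  folded <- if (inherits(newdata, "folded_ltsa")) newdata else
    fold(newdata, object$config$frames_per_patch)
  V <- folded$V
  if (nrow(V) != nrow(object$W))
    stop("dimension mismatch: folded input has ", nrow(V),
         " rows but the dictionary has ", nrow(object$W))
  W <- object$W
  .with_seed(seed, {
    H <- matrix(stats::runif(ncol(W) * ncol(V)), ncol(W), ncol(V))
    WH <- W %*% H
    H <- H * sum(V * WH) / max(sum(WH^2), 1e-300)
    obj <- numeric(iterations)
    WtV <- crossprod(W, V)          # constant while W is fixed
    WtW <- crossprod(W)
    normV2 <- sum(V^2)
    for (it in seq_len(iterations)) {
      H <- .update_h(WtV, WtW, H)
      obj[it] <- 0.5 * (normV2 - 2 * sum(H * WtV) + sum((WtW %*% H) * H))
    }
    structure(list(H = H, objective = obj, n_freq = folded$n_freq,
                   n_time = folded$n_time,
                   frames_per_patch = folded$frames_per_patch),
              class = "pcnmf_activations")
  })
}

#' Reconstruct per-source LTSAs by ratio masking
#'
#' For each source `s`, the mixture grid is multiplied by the ratio mask
#' `(W_s H_s) / (W H)` built from the features assigned to `s` (after
#' overrides), so the separated channels are nonnegative and sum to the
#' input wherever the model has support. Cells where `W H` falls below
#' `eps = 1e-12 * max(WH)` get mask 0.
#'
#' @param model A `pcnmf` model.
#' @param x The grid to separate (`prewhitened_ltsa`, `folded_ltsa`, or
#'   matrix).
#' @param activations Optional `pcnmf_activations` for `x`; computed via
#'   [predict.pcnmf()] when missing.
#' @param iterations,seed Passed to [predict.pcnmf()] when activations are
#'   computed here.
#' @return A `separated_sources` object: list of per-source grids (`sources`,
#'   each frequency x time), `labels`, `assignment`, and the axes of `x`
#'   when available.
#' @export
separate <- function(model, x, activations = NULL, iterations = 200,
                     seed = 1) {
  stopifnot(inherits(model, "pcnmf"))
  folded <- if (inherits(x, "folded_ltsa")) x else
    fold(x, model$config$frames_per_patch)
  if (is.null(activations))
    activations <- predict(model, folded, iterations = iterations,
                           seed = seed)
  H <- activations$H
  V <- folded$V
  W <- model$W
  if (ncol(H) != ncol(V) || nrow(W) != nrow(V))
    stop("shapes inconsistent between model, activations and input")
  WH <- W %*% H
  eps <- 1e-12 * max(WH)
  support <- WH > eps
  assign_eff <- source_assignment(model)
  ns <- model$config$n_sources
  sources <- vector("list", ns)
  for (s in seq_len(ns)) {
    idx <- which(assign_eff == s)
    if (!length(idx)) {
      warning("source ", s, " has no assigned features; channel is zero")
      Ps <- matrix(0, nrow(V), ncol(V))
    } else {
      num <- W[, idx, drop = FALSE] %*% H[idx, , drop = FALSE]
      mask <- matrix(0, nrow(V), ncol(V))
      mask[support] <- num[support] / WH[support]
      Ps <- V * mask
    }
    sources[[s]] <- unfold(Ps, folded$n_freq, folded$n_time)
  }
  names(sources) <- paste0("source_", seq_len(ns))
  structure(list(sources = sources,
                 labels = names(sources),
                 assignment = assign_eff,
                 freq = if (is.list(x)) x$freq else NULL,
                 time = if (is.list(x)) x$time else NULL,
                 clip_seconds = if (is.list(x)) x$clip_seconds %||% NA_real_
                                else NA_real_),
            class = "separated_sources")
}

#' Detection performance at a fixed false-positive rate
#'
#' Sweeps all score thresholds and returns the highest true-positive rate
#' whose false-positive rate does not exceed `fpr`, together with the
#' threshold achieving it. Used to score a separated channel's intensity
#' series against ground-truth activity.
#'
#' @param score Numeric score series (e.g. relative intensity).
#' @param truth Binary (0/1 or logical) labels, same length; must contain
#'   both classes.
#' @param fpr Maximum admissible false-positive rate (default 0.05).
#' @return List with `tpr`, `threshold`, `fpr` (achieved).
#' @export
evaluate_detection <- function(score, truth, fpr = 0.05) {
  truth <- as.logical(truth)
  if (length(score) != length(truth)) stop("score and truth lengths differ")
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0 || nneg == 0)
    stop("truth must contain both classes (", npos, " positives, ",
         nneg, " negatives)")
  th <- sort(unique(score), decreasing = TRUE)
  best <- list(tpr = 0, threshold = Inf, fpr = 0)
  for (t in th) {
    pred <- score >= t
    f <- sum(pred & !truth) / nneg
    if (f > fpr) next
    tp <- sum(pred & truth) / npos
    if (tp > best$tpr) best <- list(tpr = tp, threshold = t, fpr = f)
  }
  best
}

#' @export
print.pcnmf <- function(x, ...) {
  cfg <- x$config
  cat("Periodicity-coded NMF model\n")
  cat("  features: ", cfg$n_features, " (sparseness ",
      cfg$sparseness_target, ", patch ", cfg$frames_per_patch,
      " frames)\n", sep = "")
  cat("  sources: ", cfg$n_sources, "; feature counts per source: ",
      paste(tabulate(source_assignment(x), cfg$n_sources), collapse = "/"),
      "\n", sep = "")
  cat("  final layer-1 objective: ",
      format(utils::tail(x$objective, 1), digits = 6), " after ",
      cfg$iterations, " iterations\n", sep = "")
  if (length(x$overrides))
    cat("  manual overrides: ", length(x$overrides), " feature(s)\n",
        sep = "")
  invisible(x)
}

#' @export
summary.pcnmf <- function(object, ...) {
  a0 <- object$assignment
  a1 <- source_assignment(object)
  out <- list(
    config = object$config,
    features_per_source = tabulate(a1, object$config$n_sources),
    overridden = which(a0 != a1),
    feature_sparseness = apply(object$W, 2, sparseness),
    objective_initial = object$objective[1],
    objective_final = utils::tail(object$objective, 1)
  )
  class(out) <- "summary.pcnmf"
  out
}

#' @export
print.summary.pcnmf <- function(x, ...) {
  cat("PC-NMF summary\n")
  cat("  features per source:",
      paste(x$features_per_source, collapse = " / "), "\n")
  if (length(x$overridden))
    cat("  manually reassigned features:",
        paste(x$overridden, collapse = ", "), "\n")
  cat("  feature sparseness: ",
      format(mean(x$feature_sparseness), digits = 6), " (target ",
      x$config$sparseness_target, ")\n", sep = "")
  cat("  layer-1 objective: ", format(x$objective_initial, digits = 6),
      " -> ", format(x$objective_final, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
coef.pcnmf <- function(object, ...) object$W

#' Dictionary and periodicity display of a fitted model
#'
#' Shows the learned spectral features (as a heatmap of the dictionary) and
#' each feature's periodicity profile with its source assignment.
#'
#' @param x A `pcnmf` model.
#' @param ... Unused.
#' @export
plot.pcnmf <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(x$W)), seq_len(nrow(x$W)), t(x$W),
                  xlab = "feature", ylab = "folded spectral dimension",
                  main = "spectral features W", useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"))
  graphics::image(seq_len(ncol(x$Q)), seq_len(nrow(x$Q)), t(x$Q),
                  xlab = "feature", ylab = "periodicity bin",
                  main = "periodicity matrix", useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"))
  invisible(x)
}

#' @export
print.separated_sources <- function(x, ...) {
  cat("Separated sources: ", length(x$sources), " channels, ",
      nrow(x$sources[[1]]), " x ", ncol(x$sources[[1]]), " each\n", sep = "")
  en <- vapply(x$sources, sum, numeric(1))
  cat("  energy share:",
      paste(sprintf("%s %.1f%%", x$labels, 100 * en / max(sum(en), 1e-300)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Select clips recorded on the first day of each month
#'
#' Training-subset helper mirroring the common practice of fitting the
#' dictionary on a small, seasonally balanced subsample (the first day of
#' each month across the deployment).
#'
#' @param times `POSIXct` clip start times.
#' @return Logical vector marking clips on the first day of a month.
#' @export
training_subset <- function(times) {
  as.integer(format(times, "%d")) == 1L
}

#' Persist / load a PC-NMF model
#'
#' Only the spectral features, the indicator layer and the configuration are
#' needed between phases; the full object (including training activations)
#' is stored for inspection.
#'
#' @param model A `pcnmf` model.
#' @param path File path.
#' @export
write_pcnmf <- function(model, path) {
  stopifnot(inherits(model, "pcnmf"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_pcnmf
#' @export
read_pcnmf <- function(path) readRDS(path)
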