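test_that("fold/unfold use frequency-major patches with zero padding", {
  # B = 1 is the identity
  X <- matrix(runif(12), 3, 4)
  expect_equal(fold(X, 1)$V, X)
  # F = 4, T = 7, B = 3: 3 columns of length 12, last patch 2 zero frames
  Y <- matrix(1:28, 4, 7)
  fd <- fold(Y, 3)
  expect_equal(dim(fd$V), c(12, 3))
  expect_equal(fd$V[, 1], as.numeric(Y[, 1:3]))        # frequency-major
  expect_equal(fd$V[, 3], c(Y[, 7], rep(0, 8)))
  # round trip on random input
  Z <- matrix(runif(50), 5, 10)
  expect_equal(unfold(fold(Z, 4)), Z)
  expect_error(fold(Z, 0), "frames_per_patch")
})

make_periodic_mixture <- function(T_ = 240) {
  # two spectral features with analytically periodic activations
  w1 <- c(1, 1, 0, 0, 0, 0)
  w2 <- c(0, 0, 0, 0, 1, 1)
  h1 <- 1 + sin(2 * pi * (1:T_) / 24)          # 24-frame period
  h2 <- 1 + sin(2 * pi * (1:T_) / 8)           # 8-frame period
  V <- outer(w1, h1) + outer(w2, h2)
  list(V = V, w = cbind(w1, w2))
}

test_that("training separates features with distinct activation periods", {
  mx <- make_periodic_mixture()
  m <- pcnmf(mx$V, n_features = 2, n_sources = 2, frames_per_patch = 1,
             sparseness_target = 0.5, iterations = 150, seed = 2)
  # the two features must be assigned to different sources
  expect_equal(sort(unique(source_assignment(m))), c(1L, 2L))
  # and the layer-1 objective never increases
  expect_true(all(diff(m$objective) <= 1e-8 * (m$objective[1] + 1)))
  expect_true(all(diff(m$objective_layer2) <=
                    1e-8 * (m$objective_layer2[1] + 1)))
})

test_that("training is deterministic under a fixed seed", {
  mx <- make_periodic_mixture(120)
  m1 <- pcnmf(mx$V, n_features = 3, n_sources = 2, frames_per_patch = 2,
              iterations = 40, seed = 9)
  m2 <- pcnmf(mx$V, n_features = 3, n_sources = 2, frames_per_patch = 2,
              iterations = 40, seed = 9)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$assignment, m2$assignment)
})

test_that("trained features satisfy the sparseness constraint", {
  mx <- make_periodic_mixture(120)
  m <- pcnmf(mx$V, n_features = 3, n_sources = 2, frames_per_patch = 2,
             sparseness_target = 0.5, iterations = 60, seed = 4)
  sp <- apply(m$W, 2, sparseness)
  expect_true(all(abs(sp - 0.5) < 1e-6))
  expect_true(all(colSums(m$W) > 0))
})

test_that("training rejects invalid input", {
  expect_error(pcnmf(matrix(0, 4, 8), n_features = 2), "zero")
  expect_error(pcnmf(matrix(c(NA, runif(31)), 4, 8), n_features = 2),
               "finite")
  expect_warning(pcnmf(matrix(runif(24), 4, 6), n_features = 10,
                       n_sources = 2, frames_per_patch = 1,
                       iterations = 5, seed = 1), "overcomplete")
})

# small nonnegative least squares by bounded BFGS: independent oracle for
# the prediction phase
nnls_oracle <- function(W, v) {
  f <- function(h) 0.5 * sum((v - W %*% h)^2)
  g <- function(h) -crossprod(W, v - W %*% h)
  stats::optim(rep(0.5, ncol(W)), f, g, method = "L-BFGS-B",
               lower = 0)$par
}

test_that("prediction recovers activations with the dictionary fixed", {
  mx <- make_periodic_mixture(120)
  m <- pcnmf(mx$V, n_features = 3, n_sources = 2, frames_per_patch = 1,
             iterations = 80, seed = 6)
  # single input column equal to dictionary column 3: activation mass
  # concentrates on feature 3, matching bounded least squares
  v <- m$W[, 3, drop = FALSE] * 2.5
  act <- predict(m, v, iterations = 2000, seed = 1)
  expect_equal(which.max(act$H[, 1]), 3L)
  h_ref <- nnls_oracle(m$W, as.numeric(v))
  res_mult <- sum((v - m$W %*% act$H[, 1])^2)
  res_ref <- sum((v - m$W %*% h_ref)^2)
  expect_lt(res_mult, res_ref + 1e-4 * sum(v^2))
  expect_true(all(diff(act$objective) <= 1e-10 * (act$objective[1] + 1)))
})

test_that("prediction maps zero columns to zero and repeats to repeats", {
  mx <- make_periodic_mixture(120)
  m <- pcnmf(mx$V, n_features = 3, n_sources = 2, frames_per_patch = 1,
             iterations = 50, seed = 3)
  V <- cbind(mx$V[, 5], mx$V[, 5], 0)
  act <- predict(m, V, iterations = 300, seed = 2)
  expect_equal(act$H[, 3], rep(0, 3))
  expect_equal(act$H[, 1], act$H[, 2], tolerance = 1e-6)
  expect_error(predict(m, matrix(runif(10), 5, 2)), "mismatch")
})

test_that("indicator overrides are validated, recorded and applied", {
  mx <- make_periodic_mixture(120)
  m <- pcnmf(mx$V, n_features = 3, n_sources = 2, frames_per_patch = 1,
             iterations = 50, seed = 3)
  expect_identical(adjust_indicators(m, list()), m)
  m2 <- adjust_indicators(m, c("2" = 1))
  expect_equal(source_assignment(m2)[2], 1L)
  expect_equal(m2$assignment, m$assignment)   # audit copy untouched
  expect_error(adjust_indicators(m, c("99" = 1)), "feature")
  expect_error(adjust_indicators(m, c("1" = 7)), "source")
})

test_that("ratio masks conserve the mixture and honor overrides", {
  mx <- make_periodic_mixture(240)
  m <- pcnmf(mx$V, n_features = 2, n_sources = 2, frames_per_patch = 1,
             iterations = 150, seed = 2)
  sep <- separate(m, mx$V, iterations = 300, seed = 5)
  tot <- Reduce(`+`, sep$sources)
  WH <- m$W %*% predict(m, mx$V, iterations = 300, seed = 5)$H
  sup <- WH > 1e-6 * max(WH)
  expect_lt(max(abs(tot - mx$V)[sup] / pmax(mx$V[sup], 1e-12)), 1e-6)
  # all features forced to source 2: channel 2 is the whole mixture
  m_all <- adjust_indicators(m, stats::setNames(rep(2, 2), 1:2))
  expect_warning(sep2 <- separate(m_all, mx$V, iterations = 300, seed = 5),
                 "no assigned features")
  expect_true(all(sep2$sources[[1]] == 0))
  expect_equal(sep2$sources[[2]][sup], mx$V[sup], tolerance = 1e-4)
})

test_that("separation scales linearly with the input", {
  mx <- make_periodic_mixture(240)
  m <- pcnmf(mx$V, n_features = 2, n_sources = 2, frames_per_patch = 1,
             iterations = 100, seed = 2)
  s1 <- separate(m, mx$V, iterations = 200, seed = 3)
  s2 <- separate(m, 3 * mx$V, iterations = 200, seed = 3)
  expect_equal(s2$sources[[1]], 3 * s1$sources[[1]], tolerance = 1e-4)
  expect_equal(s2$sources[[2]], 3 * s1$sources[[2]], tolerance = 1e-4)
})

test_that("detection evaluation matches exhaustive threshold search", {
  # hand-built 10-frame table
  score <- c(0.9, 0.8, 0.7, 0.65, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
  truth <- c(1, 1, 0, 1, 1, 0, 0, 1, 0, 0)
  brute <- function(fpr) {
    best <- 0
    for (t in unique(score)) {
      pred <- score >= t
      if (sum(pred & !truth) / sum(!truth) <= fpr)
        best <- max(best, sum(pred & truth) / sum(truth))
    }
    best
  }
  for (fpr in c(0, 0.05, 0.2, 0.4, 1)) {
    expect_equal(evaluate_detection(score, truth, fpr)$tpr, brute(fpr))
  }
  # a perfectly separating score reaches TPR 1 at FPR 0
  expect_equal(evaluate_detection(truth + 0, truth, 0)$tpr, 1)
  # chance-level score: TPR near the FPR budget
  set.seed(10)
  s <- runif(20000); tr <- rbinom(20000, 1, 0.3)
  expect_lt(abs(evaluate_detection(s, tr, 0.05)$tpr - 0.05), 0.02)
  expect_error(evaluate_detection(s, rep(1, 20000)), "classes")
})

test_that("first-of-month training subset selects the right clips", {
  t <- as.POSIXct(c("2011-11-01 00:00:00", "2011-11-02 00:00:00",
                    "2011-12-01 23:59:30", "2012-01-15 12:00:00"),
                  tz = "UTC")
  expect_equal(training_subset(t), c(TRUE, FALSE, TRUE, FALSE))
})
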