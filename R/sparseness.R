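#' Hoyer sparseness of a nonnegative vector
#'
#' Sparseness is defined from the ratio of the L1 and L2 norms,
#' \deqn{\mathrm{sparseness}(x) = \frac{\sqrt{n} - (\sum_i |x_i|)/\sqrt{\sum_i x_i^2}}
#'   {\sqrt{n} - 1},}
#' which is 0 for a constant vector and 1 for a one-hot vector. It measures
#' the approximate fraction of zero-valued elements and is the constraint
#' applied to each learned spectral feature.
#'
#' @param x Nonnegative numeric vector, length at least 2, not all zero.
#' @return Sparseness in `[0, 1]`.
#' @examples
#' sparseness(c(1, 0, 0, 0)) # 1
#' sparseness(rep(2, 8))     # 0
#' @export
sparseness <- function(x) {
  n <- length(x)
  if (n < 2) stop("sparseness needs a vector of length >= 2")
  if (any(x < 0)) stop("sparseness is defined for nonnegative vectors")
  l2 <- sqrt(sum(x^2))
  if (l2 == 0) stop("sparseness is undefined for the zero vector")
  (sqrt(n) - sum(x) / l2) / (sqrt(n) - 1)
}

#' Project a vector onto a target sparseness level
#'
#' Finds the closest nonnegative vector (in the Euclidean sense) with the
#' requested sparseness, preserving the L2 norm of the input. This is the
#' standard alternating projection onto the intersection of the simplex-like
#' L1 constraint and the L2 sphere: each pass projects onto the L1 hyperplane,
#' rescales from the hyperplane midpoint back to the sphere, and zeroes any
#' coordinates driven negative before repeating on the reduced support.
#'
#' @param x Numeric vector (negative entries are permitted in the input; the
#'   result is nonnegative). Must not be all zero.
#' @param target Target sparseness, strictly between 0 and 1.
#' @return Nonnegative vector with `sparseness(out) == target` (within 1e-6)
#'   and the same L2 norm as `x` (within 1e-9).
#' @export
project_sparseness <- function(x, target) {
  n <- length(x)
  if (n < 2) stop("need a vector of length >= 2")
  if (!is.finite(target) || target <= 0 || target >= 1)
    stop("target sparseness must be in (0, 1)")
  l2 <- sqrt(sum(x^2))
  if (l2 == 0) stop("cannot project the zero vector")
  l1 <- l2 * (sqrt(n) - target * (sqrt(n) - 1))
  out <- .project_l1l2(x, l1, l2)
  out * (l2 / sqrt(sum(out^2)))   # pin the L2 norm exactly; ratio unchanged
}

## Projection of x onto {v >= 0, sum(v) = l1, ||v||_2 = l2} (Hoyer 2004).
.project_l1l2 <- function(x, l1, l2) {
  n <- length(x)
  v <- x + (l1 - sum(x)) / n
  zero <- logical(n)
  for (iter in seq_len(n + 1L)) {
    nz <- !zero
    k <- sum(nz)
    if (k == 0) stop("sparseness projection failed: empty support")
    if (k == 1) {         # one-hot limit: the L1 and L2 targets must agree
      v[] <- 0
      v[which(nz)] <- l2
      return(v)
    }
    m <- numeric(n)
    m[nz] <- l1 / k
    w <- v - m
    a <- sum(w^2)
    if (a < .Machine$double.eps * l2^2) {
      v <- m * (l2 / sqrt(sum(m^2)))
    } else {
      b <- 2 * sum(w * m)
      cc <- sum(m^2) - l2^2
      disc <- max(b^2 - 4 * a * cc, 0)
      alpha <- (-b + sqrt(disc)) / (2 * a)
      v <- m + alpha * w
    }
    if (all(v >= 0)) return(v)
    zero <- zero | (v < 0)
    v[zero] <- 0
    nz <- !zero
    v[nz] <- v[nz] - (sum(v) - l1) / sum(nz)
  }
  stop("sparseness projection did not converge")
}
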