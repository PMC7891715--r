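`%||%` <- function(a, b) if (is.null(a)) b else a

## strict local maxima with a minimum prominence; returns indices
.find_peaks <- function(x, prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  ok <- which(!is.na(x))
  idx <- integer(0)
  for (i in 2:(n - 1)) {
    if (is.na(x[i]) || is.na(x[i - 1]) || is.na(x[i + 1])) next
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) idx <- c(idx, i)
  }
  if (!length(idx) || prominence <= 0) return(idx)
  keep <- vapply(idx, function(i) {
    h <- x[i]
    ## walk outwards until a higher point (or the edge); prominence is the
    ## drop to the deeper of the two key saddles
    left <- x[seq_len(i - 1)]
    right <- x[seq.int(i + 1, n)]
    higher_l <- which(!is.na(left) & left > h)
    higher_r <- which(!is.na(right) & right > h)
    lmin <- if (length(higher_l)) {
      min(left[seq.int(max(higher_l), i - 1)], na.rm = TRUE)
    } else min(left, na.rm = TRUE)
    rmin <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r))], na.rm = TRUE)
    } else min(right, na.rm = TRUE)
    (h - max(lmin, rmin)) >= prominence
  }, logical(1))
  idx[keep]
}

## all permutations of 1:n (n small; used for channel-truth matching)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

## md5 of an R object via canonical serialization (version 2, no header drift)
.md5_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

## run code with a private RNG stream; restores the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}
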