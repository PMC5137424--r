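# Independent brute-force oracles used to cross-check the implementation.
# They deliberately share no code with the package internals.

# exhaustive enumeration of all length-w windows via embed()
brute_top_window <- function(segment, w) {
  max(rowMeans(embed(segment, w)))
}

# exhaustive best-window offset (0-based, leftmost maximal window)
brute_summit_offset <- function(segment, w) {
  # embed() row i holds the window starting at position i
  sums <- rowSums(embed(segment, w))
  which.max(sums) - 1L
}

# explicit loop version of threshold-and-cluster region calling
brute_regions <- function(values, thr, max_gap) {
  idx <- which(values > thr)
  if (length(idx) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  starts <- ends <- integer(0)
  cur_start <- idx[1]
  prev <- idx[1]
  for (i in idx[-1]) {
    if (i - prev > max_gap) {
      starts <- c(starts, cur_start)
      ends <- c(ends, prev)
      cur_start <- i
    }
    prev <- i
  }
  starts <- c(starts, cur_start)
  ends <- c(ends, prev)
  data.frame(start = starts - 1L, end = ends)  # 0-based half-open
}

# textbook tricube local polynomial regression, evaluated point by point
brute_loess <- function(x, y, span, degree = 2, at = x) {
  n <- length(x)
  q <- floor(n * span)
  vapply(at, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
    X <- outer(x - x0, 0:degree, `^`)
    stats::lm.wfit(X, y, w)$coefficients[1]
  }, numeric(1))
}

# exhaustive-permutation two-sided Wilcoxon rank sum p-value (tie-free data)
perm_wilcox_p <- function(x, y) {
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  n1 <- length(x)
  rk <- rank(pool)
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sel <- utils::combn(length(pool), n1)
  w_all <- apply(sel, 2, function(s) sum(rk[s])) - n1 * (n1 + 1) / 2
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# brute-force pairwise nearest-neighbor isolation
brute_isolated <- function(summits, min_distance) {
  vapply(seq_along(summits), function(i) {
    d <- abs(summits[-i] - summits[i])
    length(d) == 0 || min(d) > min_distance
  }, logical(1))
}

# small deterministic track fixture
flat_track <- function(value, len, chrom = "chrS") {
  coverage_track(rep(value, len), chrom = chrom)
}
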