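# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the defining formula, not by calling package code.

# One-sided Wilcoxon rank-sum p-value by complete enumeration of all
# C(n_a + n_b, n_a) assignments of ranks to group a (tie-free data only).
enumerate_wilcoxon_p <- function(a, b, direction = c("a_greater", "a_less")) {
  direction <- match.arg(direction)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  n_a <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  w_all <- apply(combos, 2, function(idx) sum(seq_along(pooled)[idx]))
  if (direction == "a_greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

# Bias-corrected distance correlation via explicit loops over the
# U-centering definition (Szekely & Rizzo).
brute_bcdcor <- function(x, y) {
  n <- length(x)
  A <- as.matrix(stats::dist(matrix(x)))
  B <- as.matrix(stats::dist(matrix(y)))
  ucen <- function(D) {
    U <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      U[i, j] <- D[i, j] -
        sum(D[i, -i]) / (n - 2) -
        sum(D[-j, j]) / (n - 2) +
        sum(D) / ((n - 1) * (n - 2))
    }
    U
  }
  Au <- ucen(A); Bu <- ucen(B)
  ip <- function(P, Q) sum(P * Q) / (n * (n - 3))
  ip(Au, Bu) / sqrt(ip(Au, Au) * ip(Bu, Bu))
}

# Otsu threshold by exhaustive between-class variance search over all
# candidate split points of a discrete histogram.
brute_otsu_level <- function(values, levels = 256L) {
  lo <- min(values); hi <- max(values)
  bin <- pmin(levels - 1L, floor((values - lo) / (hi - lo) * levels))
  best_k <- NA_integer_; best_v <- -Inf
  for (k in 1:(levels - 1)) {
    g0 <- bin < k; g1 <- !g0
    w0 <- mean(g0); w1 <- mean(g1)
    if (w0 == 0 || w1 == 0) next
    v <- w0 * w1 * (mean(bin[g0]) - mean(bin[g1]))^2
    if (v > best_v) { best_v <- v; best_k <- k }
  }
  lo + best_k / levels * (hi - lo)
}

# 8-connected components by breadth-first flood fill.
brute_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || jj < 1 || ii > nr || jj > nc) next
        if (mask[ii, jj] && lab[ii, jj] == 0) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Median filter by per-pixel neighbourhood sort with truncated windows.
brute_median_filter <- function(x, radius) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - radius):min(nr, i + radius)
    jj <- max(1, j - radius):min(nc, j + radius)
    out[i, j] <- stats::median(x[ii, jj])
  }
  out
}

# Mean filter by per-pixel direct averaging with truncated windows.
brute_mean_filter <- function(x, radius) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - radius):min(nr, i + radius)
    jj <- max(1, j - radius):min(nc, j + radius)
    out[i, j] <- mean(x[ii, jj])
  }
  out
}

# Gaussian overlapping coefficient by simple numerical integration on a
# fine fixed grid.
grid_overlap <- function(mu1, s1, mu2, s2, n = 200001) {
  lo <- min(mu1 - 10 * s1, mu2 - 10 * s2)
  hi <- max(mu1 + 10 * s1, mu2 + 10 * s2)
  x <- seq(lo, hi, length.out = n)
  sum(pmin(dnorm(x, mu1, s1), dnorm(x, mu2, s2))) * (x[2] - x[1])
}

# Yule-Walker AR coefficient estimate via solve() on the sample
# autocorrelation matrix (independent of the Levinson recursion).
yule_walker_ar <- function(x, order) {
  n <- length(x)
  r <- vapply(0:order, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n,
              numeric(1))
  R <- outer(1:order, 1:order, function(i, j) r[abs(i - j) + 1])
  as.numeric(solve(R, r[2:(order + 1)]))
}

circ_err <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}
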