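# Independent brute-force oracles, kept free of the code paths they check.

# biased (1/n) autocorrelation by explicit double loop
oracle_acf <- function(x, max_lag) {
  n <- length(x)
  xm <- x - mean(x)
  cc <- vapply(0:max_lag, function(k) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + xm[t] * xm[t + k]
    s / n
  }, numeric(1))
  cc / cc[1]
}

# biased cross-correlation, ccf(k) = corr(x[t+k], y[t]) convention
oracle_ccf <- function(x, y, max_lag) {
  n <- length(x)
  xm <- x - mean(x); ym <- y - mean(y)
  sx <- sqrt(sum(xm^2) / n); sy <- sqrt(sum(ym^2) / n)
  vapply(-max_lag:max_lag, function(k) {
    s <- 0
    for (t in seq_len(n)) {
      if (t + k >= 1 && t + k <= n) s <- s + xm[t + k] * ym[t]
    }
    (s / n) / (sx * sy)
  }, numeric(1))
}

# exhaustive window-checking peak oracle (four-neighbour strict rule)
oracle_peaks <- function(x) {
  n <- length(x)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (i < 3 || i > n - 2) next
    if (x[i] > x[i - 2] && x[i] > x[i - 1] && x[i] > x[i + 1] &&
        x[i] > x[i + 2]) {
      out <- c(out, i)
    }
  }
  out
}

# direct Yule-Walker solve via the Toeplitz system (biased autocovariances)
oracle_yule_walker <- function(x, p) {
  n <- length(x)
  xm <- x - mean(x)
  g <- vapply(0:p, function(k) sum(xm[seq_len(n - k)] * xm[seq_len(n - k) + k]) / n,
              numeric(1))
  solve(stats::toeplitz(g[1:p]), g[2:(p + 1)])
}
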