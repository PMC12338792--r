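# Independent brute-force oracles used to check the implementation.

# Local maxima with topographic prominence by direct definition: for each
# strict local maximum (plateau reported at its first index), walk outwards
# on each side to the nearest strictly higher sample (or the boundary),
# record the minimum seen on each walk, and subtract the higher minimum.
oracle_peaks <- function(x, noise_floor, prominence) {
  n <- length(x)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] <= x[i - 1]) next
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (j == n || x[j + 1] >= x[i]) next
    lmin <- x[i]
    for (k in (i - 1):1) {
      if (x[k] > x[i]) break
      lmin <- min(lmin, x[k])
    }
    rmin <- x[i]
    for (k in (j + 1):n) {
      if (x[k] > x[i]) break
      rmin <- min(rmin, x[k])
    }
    p <- x[i] - max(lmin, rmin)
    if (x[i] > noise_floor && p >= prominence) peaks <- c(peaks, i)
  }
  peaks
}

# Exact two-sided Mann-Whitney p by full enumeration of label assignments
# (tie-free samples only). U counts pairs (a, b) with a > b.
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  na <- length(a); nb <- length(b)
  u_of <- function(xa, xb) sum(outer(xa, xb, ">"))
  u_obs <- u_of(a, b)
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Classic one-way ANOVA by explicit sums of squares.
oracle_anova <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# OLS slope/intercept by explicit normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}
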