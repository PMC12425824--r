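# Independent brute-force oracles. These re-derive every statistic from first
# principles with plain loops so the package implementations are checked
# against code that shares nothing with them.

# deviation pipeline: loop-based, materializes E, follows the definitions
bf_deviation_z <- function(X, members, map) {
  X <- as.matrix(X)
  n_peaks <- nrow(X); n_cells <- ncol(X)
  E <- matrix(0, n_peaks, n_cells)
  tot <- sum(X)
  for (i in seq_len(n_peaks)) for (j in seq_len(n_cells))
    E[i, j] <- sum(X[i, ]) * sum(X[, j]) / tot
  set_dev <- function(idx) {
    y <- numeric(n_cells)
    for (j in seq_len(n_cells)) {
      o <- 0; e <- 0
      for (i in idx) { o <- o + X[i, j]; e <- e + E[i, j] }
      y[j] <- if (e > 0) (o - e) / e else NA_real_
    }
    y
  }
  y <- set_dev(members)
  B <- ncol(map)
  bg <- matrix(NA_real_, B, n_cells)
  for (b in seq_len(B)) bg[b, ] <- set_dev(map[members, b])
  d <- z <- numeric(n_cells)
  for (j in seq_len(n_cells)) {
    mu <- mean(bg[, j])
    s <- sqrt(sum((bg[, j] - mu)^2) / (B - 1))
    d[j] <- y[j] - mu
    z[j] <- if (!is.na(s) && s > 0) d[j] / s else NA_real_
  }
  list(y = y, d = d, z = z)
}

# one-sided (greater) rank-sum p by full enumeration of group assignments
bf_wilcoxon_greater <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mean(u_all >= u_obs)
}

# upper-tail hypergeometric p by exhaustive enumeration over overlaps
bf_hypergeom_upper <- function(q, K, N, n_draw) {
  ks <- 0:n_draw
  probs <- choose(K, ks) * choose(N - K, n_draw - ks) / choose(N, n_draw)
  sum(probs[ks >= q])
}

# product-limit estimate by hand
bf_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ut, survival = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# log-rank chi-square by table-by-table evaluation
bf_logrank <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb)
  grp_a <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    n <- sum(time >= t); n_a <- sum(time >= t & grp_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp_a)
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Spearman rho as rank-then-Pearson
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
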