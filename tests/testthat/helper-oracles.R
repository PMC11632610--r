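# Independent brute-force oracles used to pin expected values. These are
# deliberately naive (explicit loops, closed forms) and share no code with
# the package implementations they check.

# step-up BH by the direct formula adj_(i) = min_{k >= i} p_(k) * n / k
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(ps[i:n] * n / (i:n))
  pmin(adj, 1)[order(o)]
}

# paired SAM with exhaustive sign-flip enumeration, all loops explicit
oracle_sam_paired <- function(diffs, s0, n_delta = 200) {
  G <- nrow(diffs); n <- ncol(diffs)
  dfun <- function(x) mean(x) / (stats::sd(x) / sqrt(n) + s0)
  d_obs <- apply(diffs, 1, dfun)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  d_null <- matrix(0, G, nrow(signs))
  for (b in seq_len(nrow(signs)))
    d_null[, b] <- apply(sweep(diffs, 2, signs[b, ], `*`), 1, dfun)
  grid <- seq(0, max(abs(d_obs)), length.out = n_delta)
  qs <- stats::quantile(d_obs, c(0.25, 0.75))
  pi0 <- min(1, mean(d_null >= qs[1] & d_null <= qs[2]) / 0.5)
  fdr_grid <- vapply(grid, function(delta) {
    obs <- sum(abs(d_obs) >= delta)
    med <- stats::median(apply(d_null, 2, function(cl) sum(abs(cl) >= delta)))
    min(1, pi0 * med / max(obs, 1))
  }, numeric(1))
  q <- vapply(abs(d_obs), function(a) min(fdr_grid[grid <= a]), numeric(1))
  list(d = d_obs, q = q, pi0 = pi0, grid = grid, fdr_grid = fdr_grid)
}

# unpaired SAM with exhaustive label enumeration
oracle_sam_unpaired <- function(x1, x2, s0, n_delta = 200) {
  X <- cbind(x1, x2)
  n1 <- ncol(x1); n2 <- ncol(x2); n <- n1 + n2
  dfun <- function(g1) {
    a <- X[, g1, drop = FALSE]; b <- X[, setdiff(seq_len(n), g1), drop = FALSE]
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    ss <- rowSums((a - m1)^2) + rowSums((b - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) * ss / (n - 2))
    (m2 - m1) / (s + s0)
  }
  d_obs <- dfun(seq_len(n1))
  combos <- utils::combn(n, n1)
  d_null <- matrix(0, nrow(X), ncol(combos))
  for (b in seq_len(ncol(combos))) d_null[, b] <- dfun(combos[, b])
  grid <- seq(0, max(abs(d_obs)), length.out = n_delta)
  qs <- stats::quantile(d_obs, c(0.25, 0.75))
  pi0 <- min(1, mean(d_null >= qs[1] & d_null <= qs[2]) / 0.5)
  fdr_grid <- vapply(grid, function(delta) {
    obs <- sum(abs(d_obs) >= delta)
    med <- stats::median(apply(d_null, 2, function(cl) sum(abs(cl) >= delta)))
    min(1, pi0 * med / max(obs, 1))
  }, numeric(1))
  q <- vapply(abs(d_obs), function(a) min(fdr_grid[grid <= a]), numeric(1))
  list(d = d_obs, q = q, pi0 = pi0)
}

# upper-tail hypergeometric P(X >= k) by direct summation of the mass
oracle_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Pearson r by the direct covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}
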