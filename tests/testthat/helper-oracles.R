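# Independent oracles, deliberately written as direct transcriptions of
# the defining formulas (loops, closed forms), not sharing code with the
# package implementation.

# brute-force topological overlap by triple loop
tom_brute <- function(a) {
  n <- nrow(a)
  w <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    w[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  w
}

# survival function of the m-th largest of K uniform spacings:
# P(X_(m) > t) = sum_{j=m}^{floor(1/t)} (-1)^(j-m) C(j-1, m-1) C(K, j) (1 - j t)^(K-1)
spacing_surv <- function(t, m, K) {
  jmax <- min(K, floor(1 / t))
  if (jmax < m) return(0)
  j <- m:jmax
  sum((-1)^(j - m) * choose(j - 1, m - 1) * choose(K, j) * (1 - j * t)^(K - 1))
}

# exact quantile of the m-th largest spacing by numerical CDF inversion
spacing_quantile <- function(p, m, K) {
  stats::uniroot(function(t) (1 - spacing_surv(t, m, K)) - p,
                 interval = c(1e-12, 1 - 1e-12), tol = 1e-10)$root
}

# exact two-sided signed-rank p-value by full enumeration of sign flips
# (no ties, no zeros), matching the exact convention of wilcox.test
signed_rank_exact_p <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  t_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- as.numeric(signs %*% rk)
  min(1, 2 * min(mean(t_all <= t_obs), mean(t_all >= t_obs)))
}

# average precision computed the slow explicit way
ap_brute <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]
  ps <- c()
  for (i in seq_along(truth)) if (truth[i]) ps <- c(ps, sum(truth[1:i]) / i)
  mean(ps)
}
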