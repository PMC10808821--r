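# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and p.adjust/lm where those are the
# implementation) so that equivalence checks are two-route.

# Benjamini-Hochberg by direct definition: sort ascending, scale p * m / rank,
# enforce monotonicity by cumulative minimum from the largest rank.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# OLS by the normal equations, no lm machinery.
ols_brute <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Shannon index by direct summation.
shannon_brute <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# Bray-Curtis by the defining formula.
bray_brute <- function(u, v) sum(abs(u - v)) / sum(u + v)

# Classical MDS via a dense eigendecomposition of the double-centered matrix.
pcoa_brute <- function(D, k) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(eg$values > 1e-12)
  k <- min(k, length(pos))
  coords <- eg$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(eg$values[pos[seq_len(k)]]), k)
  list(coords = coords, values = eg$values)
}

# Tertile assignment by explicit rank-and-cut with downward tie resolution,
# written against the definition rather than the package internals.
tertile_brute <- function(scores) {
  n <- length(scores)
  srt <- sort(scores)
  c1 <- srt[ceiling(n / 3)]
  c2 <- srt[ceiling(2 * n / 3)]
  vapply(scores, function(s) {
    if (s <= c1) "T1" else if (s <= c2) "T2" else "T3"
  }, character(1))
}
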