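# Shared fixtures, all generated in code under fixed seeds.

rstd <- function(n, T, seed) {
  set.seed(seed)
  standardizeRows(matrix(rnorm(n * T), n, T))
}

# AR(1) rows with optional cross-node correlation, standardized
rar1 <- function(n, T, phi, seed, Sigma = diag(n), burn = 50L) {
  set.seed(seed)
  R <- chol(Sigma)
  eps <- crossprod(R, matrix(rnorm(n * (T + burn)), n, T + burn))
  x <- matrix(0, n, T + burn)
  x[, 1] <- eps[, 1]
  for (j in 2:(T + burn)) x[, j] <- phi * x[, j - 1] + eps[, j]
  standardizeRows(x[, (burn + 1):(T + burn), drop = FALSE])
}

# brute-force double-loop segment covariance (population divisor)
bruteSegCov <- function(v, i, j) {
  n <- nrow(v); m <- j - i + 1
  S <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    acc <- 0
    for (l in i:j) acc <- acc + v[a, l] * v[b, l]
    S[a, b] <- acc / m
  }
  S
}

lag1Autocor <- function(y) {
  T <- length(y)
  sum(y[-T] * y[-1]) / sum(y^2)
}
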