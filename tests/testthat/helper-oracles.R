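# Independent brute-force oracles and shared fixtures, kept deliberately
# naive so they cannot share a defect with the implementation they check.

noiseless_pair <- function(case) simulate_case(case, a = 1, noise = 0)

random_pair <- function(n = 12, seed = 1) {
  set.seed(seed)
  list(x = rnorm(n), y = rnorm(n))
}

# H K H by explicit matrix product, the algebraic definition of centering
oracle_double_center <- function(K) {
  T0 <- nrow(K)
  H <- diag(T0) - matrix(1 / T0, T0, T0)
  H %*% K %*% H
}

# naive O(n^2) double-loop sample distance correlation (biased V-statistic)
oracle_dcor <- function(x, y) {
  n <- length(x)
  a <- outer(x, x, function(u, v) abs(u - v))
  b <- outer(y, y, function(u, v) abs(u - v))
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  sqrt(dcov2) / sqrt(sqrt(dvx * dvy))
}

# pair-enumeration Kendall tau-b with tie correction
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx * sy > 0) conc <- conc + 1
    if (sx * sy < 0) disc <- disc + 1
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}
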