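# Independent oracles used across the test files. These deliberately
# avoid the package's own computational paths.

# Brute-force Sobol indices of the g-function by grid quadrature,
# d <= 3. D = int f^2 - 1; V_i integrates out the other factors first.
quadrature_g_indices <- function(a, n_grid = 2000L) {
  d <- length(a)
  stopifnot(d <= 3)
  # midpoint rule nodes
  x <- (seq_len(n_grid) - 0.5) / n_grid
  gi <- lapply(seq_len(d), function(i) (abs(4 * x - 2) + a[[i]]) / (1 + a[[i]]))
  m1 <- vapply(gi, mean, numeric(1))          # all equal 1 analytically
  m2 <- vapply(gi, function(v) mean(v^2), numeric(1))
  D <- prod(m2) - prod(m1)^2
  V <- vapply(seq_len(d), function(i) {
    # E[ E(f | x_i)^2 ] - f0^2 with the product structure
    mean(gi[[i]]^2) * prod(m1[-i])^2 - prod(m1)^2
  }, numeric(1))
  Vmi <- vapply(seq_len(d), function(i) {
    # closed index of the complement group
    prod(m2[-i]) * m1[[i]]^2 - prod(m1)^2
  }, numeric(1))
  list(first = V / D, total = 1 - Vmi / D, D = D)
}

# Literal three-term expansion of the biased HSIC estimator, written
# with explicit loops over the kernel evaluations.
hsic_expansion_oracle <- function(Kx, Ku) {
  n <- nrow(Kx)
  t1 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) t1 <- t1 + Kx[i, j] * Ku[i, j]
  t1 <- t1 / n^2
  t2 <- (sum(Kx) / n^2) * (sum(Ku) / n^2)
  t3 <- 0
  for (i in seq_len(n)) {
    t3 <- t3 + (sum(Kx[i, ]) / n) * (sum(Ku[i, ]) / n)
  }
  t3 <- 2 * t3 / n
  t1 + t2 - t3
}

# Kullback-Leibler divergence (mutual information) of a bivariate
# Gaussian with correlation rho
gaussian_kl <- function(rho) -0.5 * log(1 - rho^2)

random_correlated_pair <- function(n, rho) {
  x <- rnorm(n)
  list(x = x, u = rho * x + sqrt(1 - rho^2) * rnorm(n))
}

# small deterministic time course used by several io / pipeline tests
toy_timecourse <- function() {
  tibble::tibble(
    gene = rep(c("A", "B"), each = 5),
    hour = rep(c(1, 3, 6, 12, 24), 2),
    fold_change = c(1, 3, 2, 4, 5, -1, -2.5, -1.5, -0.5, 0.5)
  )
}

signif_like <- function(x) as.numeric(formatC(x, digits = 10, format = "g"))
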