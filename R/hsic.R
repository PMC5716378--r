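#' Gram matrix of a kernel over a sample
#'
#' Pairwise kernel evaluations for one variable. Supported families:
#' `rbf` \eqn{k(x,y) = \exp(-\|x-y\|^2 / (2\sigma^2))}, `laplace`
#' \eqn{k(x,y) = \exp(-\|x-y\|_1 / \sigma)} and `linear`
#' \eqn{k(x,y) = \langle x, y\rangle}. The default bandwidth is the
#' median heuristic (see [median_heuristic_bandwidth()]).
#'
#' @param samples Numeric vector (or single-column matrix) of at
#'   least 2 observations.
#' @param family `"rbf"`, `"laplace"` or `"linear"`.
#' @param bandwidth Positive kernel scale, or `"median-heuristic"`.
#' @return A symmetric positive semi-definite `n` x `n` matrix.
#' @export
gram_matrix <- function(samples, family = "rbf", bandwidth = "median-heuristic") {
  family <- match.arg(family, c("rbf", "laplace", "linear"))
  x <- as.numeric(samples)
  if (length(x) < 2L) stop_input("Need at least 2 samples.")
  if (family == "linear") return(outer(x, x))
  if (identical(bandwidth, "median-heuristic")) {
    bandwidth <- median_heuristic_bandwidth(x)
  }
  check_number(bandwidth, "bandwidth")
  if (bandwidth <= 0) stop_input("`bandwidth` must be positive.")
  d <- outer(x, x, "-")
  if (family == "rbf") exp(-(d * d) / (2 * bandwidth^2)) else exp(-abs(d) / bandwidth)
}

#' Centering matrix
#'
#' The projection \eqn{H_{ij} = \delta_{ij} - 1/n} that removes the
#' sample mean in feature space; idempotent with zero row sums.
#'
#' @param n Matrix dimension, at least 1.
#' @export
centering_matrix <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop_input("`n` must be a single integer >= 1.")
  }
  n <- as.integer(n)
  diag(n) - 1 / n
}

#' Median-heuristic kernel bandwidth
#'
#' The median of all pairwise distances of the sample (absolute
#' differences for one-dimensional data, serving both the Euclidean
#' and L1 metrics). Scales linearly with the data, which makes the
#' resulting HSIC index invariant to per-variable affine rescaling.
#'
#' @param samples Numeric vector, at least 2 values, not all equal.
#' @return A positive bandwidth.
#' @export
median_heuristic_bandwidth <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 2L) stop_input("Need at least 2 samples.")
  d <- abs(outer(x, x, "-"))
  d <- d[upper.tri(d)]
  bw <- median(d)
  if (bw <= 0) {
    d <- d[d > 0]
    if (length(d) == 0L) {
      stop_degenerate("All samples identical; bandwidth is undefined.")
    }
    bw <- median(d)
  }
  bw
}

# three-term expansion of the biased HSIC estimator, O(n^2), used by
# the pipelines where full matrix products would dominate the runtime
hsic_from_grams <- function(Kx, Ku) {
  n <- nrow(Kx)
  mean(Kx * Ku) + mean(Kx) * mean(Ku) - 2 * mean(rowMeans(Kx) * rowMeans(Ku))
}

#' Hilbert-Schmidt independence criterion
#'
#' The biased empirical HSIC
#' \eqn{\mathrm{HSIC}_n(X,U) = \mathrm{Tr}(K_X H K_U H) / n^2},
#' the squared Hilbert-Schmidt norm of the empirical cross-covariance
#' operator between the kernel embeddings of the two variables. It is
#' zero (in the population) if and only if the variables are
#' independent, for universal kernels.
#'
#' @param x,u Paired numeric samples, n >= 4.
#' @param family_x,family_u Kernel family for each variable.
#' @param bandwidth_x,bandwidth_u Kernel scale or
#'   `"median-heuristic"`.
#' @return A non-negative scalar.
#' @export
hsic <- function(x, u, family_x = "rbf", family_u = family_x,
                 bandwidth_x = "median-heuristic",
                 bandwidth_u = "median-heuristic") {
  if (length(x) != length(u)) stop_input("`x` and `u` must have equal length.")
  n <- length(x)
  if (n < 4L) stop_input("Need at least 4 paired samples.")
  Kx <- gram_matrix(x, family_x, bandwidth_x)
  Ku <- gram_matrix(u, family_u, bandwidth_u)
  H <- centering_matrix(n)
  sum(diag(Kx %*% H %*% Ku %*% H)) / n^2
}

#' Kernel distance-correlation sensitivity index
#'
#' The HSIC-based sensitivity index: the kernel distance correlation
#' \deqn{R^2(X, U) = \frac{\mathrm{HSIC}(X,U)}
#'   {\sqrt{\mathrm{HSIC}(X,X)\,\mathrm{HSIC}(U,U)}}}
#' reported as `R` in `[0, 1]`: 0 means the output does not depend on
#' the factor, 1 full dependence. Non-linear kernels (rbf, laplace)
#' capture relations a linear kernel misses.
#'
#' @inheritParams hsic
#' @param factor Optional factor name for the result row.
#' @return A one-row tibble: `factor`, `method`, `order`, `value`,
#'   `n`.
#' @export
hsic_index <- function(x, u, family_x = "rbf", family_u = family_x,
                       bandwidth_x = "median-heuristic",
                       bandwidth_u = "median-heuristic",
                       factor = NA_character_) {
  if (length(x) != length(u)) stop_input("`x` and `u` must have equal length.")
  if (length(x) < 4L) stop_input("Need at least 4 paired samples.")
  Kx <- gram_matrix(x, family_x, bandwidth_x)
  Ku <- gram_matrix(u, family_u, bandwidth_u)
  value <- hsic_r_from_grams(Kx, Ku)
  tibble(
    factor = factor,
    method = paste0("hsic:", family_x),
    order = "first",
    value = value,
    n = length(x)
  )
}

hsic_r_from_grams <- function(Kx, Ku) {
  hxu <- hsic_from_grams(Kx, Ku)
  hxx <- hsic_from_grams(Kx, Kx)
  huu <- hsic_from_grams(Ku, Ku)
  if (hxx <= 0 || huu <= 0) {
    stop_degenerate("Constant variable: self-HSIC is zero.")
  }
  hxu / sqrt(hxx * huu)
}

#' Permutation significance test for the HSIC index
#'
#' Compares the observed kernel distance correlation with its null
#' distribution under random permutations of the output, a diagnostic
#' for whether an index magnitude exceeds what independence alone
#' would produce. Gram matrices are computed once and reindexed per
#' permutation.
#'
#' @inheritParams hsic
#' @param n_perm Number of permutations.
#' @param rng_seed Integer seed.
#' @return A list with `statistic` (observed R), `null` (permutation
#'   values) and `p_value`.
#' @export
hsic_test <- function(x, u, family_x = "rbf", family_u = family_x,
                      n_perm = 200L, rng_seed = NULL) {
  if (length(x) != length(u)) stop_input("`x` and `u` must have equal length.")
  n <- length(x)
  if (n < 4L) stop_input("Need at least 4 paired samples.")
  Kx <- gram_matrix(x, family_x)
  Ku <- gram_matrix(u, family_u)
  obs <- hsic_r_from_grams(Kx, Ku)
  null <- with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      hsic_r_from_grams(Kx, Ku[p, p, drop = FALSE])
    }, numeric(1))
  })
  list(
    statistic = obs,
    null = null,
    p_value = (1 + sum(null >= obs)) / (n_perm + 1)
  )
}
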