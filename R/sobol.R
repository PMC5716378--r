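#' Build a pick-freeze Monte Carlo design
#'
#' Generates the paired input matrices used by the pick-freeze Sobol
#' estimators: two independent `n` x `d` matrices `A` and `B` of
#' uniform unit-cube samples. For factor `i` the hybrid matrix
#' `AB_i` is `A` with column `i` replaced by column `i` of `B`
#' (materialised lazily by [pickfreeze_hybrid()]). Estimating all
#' first-order and total indices costs `(d + 2) * n` model runs.
#'
#' @param n Number of Monte Carlo rows, at least 2.
#' @param d Number of input factors, at least 1.
#' @param rng_seed Integer seed for reproducibility.
#' @return An object of class `pickfreeze_design`: a list with
#'   elements `A`, `B`, `n`, `d`, `rng_seed`.
#' @export
build_design <- function(n, d, rng_seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2) {
    stop_input("`n` must be a single integer >= 2.")
  }
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1) {
    stop_input("`d` must be a single integer >= 1.")
  }
  n <- as.integer(n); d <- as.integer(d)
  m <- with_seed(rng_seed, matrix(runif(2L * n * d), nrow = 2L * n, ncol = d))
  structure(
    list(A = m[seq_len(n), , drop = FALSE],
         B = m[n + seq_len(n), , drop = FALSE],
         n = n, d = d, rng_seed = rng_seed),
    class = "pickfreeze_design"
  )
}

#' Assemble a pick-freeze design from observed data rows
#'
#' Splits the rows of a unit-cube sample matrix into two halves,
#' taking the first half as `A` and the second as `B`. This is how
#' the pipelines feed bootstrapped expression samples to the Sobol
#' estimators: the data stand in for the Monte Carlo design and the
#' hybrid rows are re-evaluated through the model.
#'
#' @param x Numeric matrix with entries in `[0, 1]`, at least 4 rows.
#' @return A `pickfreeze_design`.
#' @export
design_from_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4L) stop_input("Need at least 4 rows to split into A and B.")
  if (anyNA(x) || any(x < 0 | x > 1)) {
    stop_domain("Design entries must lie in [0, 1].")
  }
  n <- nrow(x) %/% 2L
  structure(
    list(A = x[seq_len(n), , drop = FALSE],
         B = x[n + seq_len(n), , drop = FALSE],
         n = n, d = ncol(x), rng_seed = NULL),
    class = "pickfreeze_design"
  )
}

#' Hybrid matrix of a pick-freeze design
#'
#' Returns `A` with the columns in `which` replaced by the matching
#' columns of `B`. A single index gives the classic first-order/total
#' hybrid; several indices give the grouped (closed) design.
#'
#' @param design A [build_design()] object.
#' @param which Integer indices of the columns to swap.
#' @export
pickfreeze_hybrid <- function(design, which) {
  stopifnot(inherits(design, "pickfreeze_design"))
  if (length(which) < 1L || any(which < 1 | which > design$d)) {
    stop_input("`which` must be a non-empty subset of 1..d.")
  }
  ab <- design$A
  ab[, which] <- design$B[, which, drop = FALSE]
  ab
}

#' Centre a model output vector
#'
#' Subtracts the sample mean. The Saltelli (2002) estimator is
#' sensitive to a largely non-centred output, so the output is centred
#' automatically before that estimator is applied; centring leaves
#' every variance-based index unchanged.
#'
#' @param u Numeric output vector.
#' @return `u - mean(u)`.
#' @export
center_output <- function(u) {
  if (!is.numeric(u) || length(u) < 1L) {
    stop_input("`u` must be a non-empty numeric vector.")
  }
  u - mean(u)
}

sobol_methods <- c("sobol1993", "saltelli2002", "mauntz2007", "jansen", "martinez")

#' Pick-freeze estimation of first-order and total Sobol indices
#'
#' Estimates, for every input factor, the first-order index
#' \eqn{S_i = D_i / D} (variance share of the factor alone) and the
#' total index \eqn{T_i} (share including all interactions) from a
#' pick-freeze design, in one of five classical estimator variants:
#'
#' * `jansen`: \eqn{T_i = \sum (f(A)-f(AB_i))^2 / (2nD)},
#'   \eqn{S_i = 1 - \sum (f(B)-f(AB_i))^2 / (2nD)}.
#' * `saltelli2002`: \eqn{S_i = (\frac1n\sum f(B) f(AB_i) - f_0^2)/D},
#'   \eqn{T_i = 1 - (\frac1n\sum f(A) f(AB_i) - f_0^2)/D}, computed on
#'   centred output.
#' * `mauntz2007`: \eqn{S_i = \frac1n\sum f(B)(f(AB_i)-f(A))/D},
#'   \eqn{T_i = \frac1n\sum f(A)(f(A)-f(AB_i))/D}.
#' * `martinez`: correlation-coefficient forms
#'   \eqn{S_i = \mathrm{cor}(f(B), f(AB_i))},
#'   \eqn{T_i = 1 - \mathrm{cor}(f(A), f(AB_i))}.
#' * `sobol1993`: the original Monte Carlo form
#'   \eqn{S_i = (\frac1n\sum f(B) f(AB_i) - f_0^2)/D} with
#'   \eqn{f_0^2} estimated as `mean(f(A)) * mean(f(B))`.
#'
#' The total variance `D` is estimated from the pooled `A` and `B`
#' evaluations. Estimates may be slightly negative by Monte Carlo
#' noise; they are returned unclipped and flagged.
#'
#' @param model A function taking a matrix of unit-cube rows and
#'   returning one output value per row.
#' @param design A [build_design()] object.
#' @param method One of `"sobol1993"`, `"saltelli2002"`, `"mauntz2007"`,
#'   `"jansen"`, `"martinez"`.
#' @param factors Optional character vector of factor names.
#' @return A tibble with columns `factor`, `method`, `order`
#'   (`"first"` or `"total"`), `value`, `n`, and `negative` (flag for
#'   below-zero estimates).
#' @export
estimate_sobol <- function(model, design, method = "jansen", factors = NULL) {
  stopifnot(inherits(design, "pickfreeze_design"))
  method <- match.arg(method, sobol_methods)
  d <- design$d; n <- design$n
  if (is.null(factors)) factors <- paste0("x", seq_len(d))
  if (length(factors) != d) stop_input("`factors` must have one name per column.")

  yA <- as.numeric(model(design$A))
  yB <- as.numeric(model(design$B))
  if (length(yA) != n || length(yB) != n) {
    stop_input("`model` must return one value per design row.")
  }
  yAB <- vapply(seq_len(d),
                function(i) as.numeric(model(pickfreeze_hybrid(design, i))),
                numeric(n))
  est <- sobol_indices_from_evals(yA, yB, yAB, method)
  tibble(
    factor = rep(factors, 2L),
    method = method,
    order = rep(c("first", "total"), each = d),
    value = c(est$first, est$total),
    n = n,
    negative = c(est$first, est$total) < 0
  )
}

# core index arithmetic shared by the design and data routes
sobol_indices_from_evals <- function(yA, yB, yAB, method) {
  n <- length(yA)
  pooled <- c(yA, yB)
  D <- mean(pooled^2) - mean(pooled)^2
  if (!is.finite(D) || D <= .Machine$double.eps * max(1, mean(pooled^2))) {
    stop_degenerate("Model output has zero variance; indices are undefined.")
  }
  if (method == "saltelli2002") {
    mu <- mean(pooled)
    yA <- yA - mu; yB <- yB - mu; yAB <- yAB - mu
    f02 <- mean(yA) * mean(yB)
    first <- (colMeans(yB * yAB) - f02) / D
    total <- 1 - (colMeans(yA * yAB) - f02) / D
  } else if (method == "sobol1993") {
    # empirical-covariance form: subtracting per-vector means removes
    # the O(f0^2/sqrt(n)) noise of the plain f0^2 plug-in
    k <- (n - 1) / n
    first <- apply(yAB, 2L, function(v) k * stats::cov(yB, v)) / D
    total <- 1 - apply(yAB, 2L, function(v) k * stats::cov(yA, v)) / D
  } else if (method == "jansen") {
    total <- colMeans((yA - yAB)^2) / (2 * D)
    first <- 1 - colMeans((yB - yAB)^2) / (2 * D)
  } else if (method == "mauntz2007") {
    # centred output; the raw form is badly conditioned for
    # non-centred models, like the saltelli2002 estimator
    mu <- mean(pooled)
    yA <- yA - mu; yB <- yB - mu; yAB <- yAB - mu
    first <- colMeans(yB * (yAB - yA)) / D
    total <- colMeans(yA * (yA - yAB)) / D
  } else { # martinez
    first <- apply(yAB, 2L, function(v) cor(yB, v))
    total <- 1 - apply(yAB, 2L, function(v) cor(yA, v))
  }
  list(first = as.numeric(first), total = as.numeric(total))
}

#' Closed (grouped) Sobol index of a subset of factors
#'
#' Pick-freeze estimate of the closed index of a factor group: all
#' group columns are swapped together, so the index measures the
#' variance share explained by the group jointly (a single-factor
#' group reduces to the first-order index). The group of all factors
#' has closed index 1 by the normalisation of the variance
#' decomposition.
#'
#' @inheritParams estimate_sobol
#' @param group Non-empty integer vector of factor indices.
#' @return A one-row tibble like [estimate_sobol()], with
#'   `order = "closed"`.
#' @export
estimate_sobol_order <- function(model, design, group, factors = NULL) {
  stopifnot(inherits(design, "pickfreeze_design"))
  if (length(group) < 1L) stop_input("`group` must be non-empty.")
  group <- unique(as.integer(group))
  if (any(group < 1 | group > design$d)) {
    stop_input("`group` indices must lie in 1..d.")
  }
  if (is.null(factors)) factors <- paste0("x", seq_len(design$d))
  yA <- as.numeric(model(design$A))
  yB <- as.numeric(model(design$B))
  yABg <- as.numeric(model(pickfreeze_hybrid(design, group)))
  pooled <- c(yA, yB)
  D <- mean(pooled^2) - mean(pooled)^2
  if (!is.finite(D) || D <= .Machine$double.eps * max(1, mean(pooled^2))) {
    stop_degenerate("Model output has zero variance; indices are undefined.")
  }
  mu <- mean(pooled)
  yA <- yA - mu; yB <- yB - mu; yABg <- yABg - mu
  value <- (mean(yB * yABg) - mean(yA) * mean(yB)) / D
  tibble(
    factor = paste(factors[group], collapse = "+"),
    method = "saltelli2002",
    order = "closed",
    value = value,
    n = design$n,
    negative = value < 0
  )
}
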