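#' The g-function benchmark model
#'
#' The multiplicative benchmark function
#' \deqn{f(x) = \prod_{i=1}^{d} \frac{|4x_i - 2| + a_i}{1 + a_i}}
#' defined on the unit cube \eqn{[0,1]^d}. It is non-linear and
#' non-monotone, its mean over the cube is exactly 1, and its Sobol
#' indices are available in closed form (see
#' [g_function_analytic_indices()]), which makes it the standard
#' test model for global sensitivity estimators. The importance
#' coefficients `a` control how much each factor matters: lower
#' \eqn{a_i} means a more important factor \eqn{x_i}.
#'
#' @param x A numeric vector of length `d`, or a matrix with `d`
#'   columns whose rows are evaluation points. All entries must lie in
#'   `[0, 1]`.
#' @param a Numeric vector of non-negative importance coefficients,
#'   one per input factor.
#' @return A numeric scalar (or one value per row of `x`), always
#'   non-negative.
#' @examples
#' g_function(c(0.5, 0.5), a = c(0, 0))   # 0: |4*0.5 - 2| = 0
#' g_function(c(1, 1, 1), a = c(0, 0, 0)) # 8: each factor equals 2
#' @export
g_function <- function(x, a) {
  check_importance(a)
  d <- length(a)
  if (is.null(dim(x))) {
    if (length(x) != d) {
      stop_input(sprintf(
        "`x` has length %d but the model has %d factors.", length(x), d
      ))
    }
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != d) {
    stop_input(sprintf(
      "`x` has %d columns but the model has %d factors.", ncol(x), d
    ))
  }
  if (anyNA(x) || any(x < 0 | x > 1)) {
    stop_domain("All components of `x` must lie in [0, 1].")
  }
  out <- rep(1, nrow(x))
  for (i in seq_len(d)) {
    out <- out * (abs(4 * x[, i] - 2) + a[[i]]) / (1 + a[[i]])
  }
  if (nrow(x) == 1L) out[[1L]] else out
}

check_importance <- function(a) {
  if (!is.numeric(a) || length(a) < 1L || anyNA(a)) {
    stop_input("`a` must be a non-empty numeric vector.")
  }
  if (any(a < 0)) {
    stop_domain("All importance coefficients `a` must be >= 0.")
  }
  invisible(a)
}

#' Draw random importance coefficients for the g-function
#'
#' Coefficients are drawn independently and uniformly on `[0, 1]`,
#' one per input factor (gene). Drawing them at random makes the
#' benchmark model agnostic to which gene matters most while keeping
#' the realised importances recoverable from the seed.
#'
#' @param d Number of input factors (e.g. 18 genes for the static
#'   experiment, 71 for the time course).
#' @param rng_seed Integer seed; the same seed always reproduces the
#'   same coefficients.
#' @return Numeric vector of length `d` with values in `[0, 1]`.
#' @export
draw_importance_coefficients <- function(d, rng_seed = NULL) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1) {
    stop_input("`d` must be a single integer >= 1.")
  }
  d <- as.integer(d)
  with_seed(rng_seed, runif(d))
}

#' Analytic Sobol indices of the g-function
#'
#' Closed-form first-order and total-order Sobol indices of the
#' g-function with coefficients `a`. With per-factor partial variance
#' \eqn{V_i = (1/3)/(1 + a_i)^2}, the total variance is
#' \eqn{D = \prod_j (1 + V_j) - 1}, the first-order index is
#' \eqn{S_i = V_i / D} and the total index is
#' \eqn{T_i = 1 - (\prod_{j \ne i}(1 + V_j) - 1)/D}.
#' These closed forms serve as the independent oracle against which
#' the Monte Carlo estimators are validated; they are themselves
#' checked against brute-force quadrature in the test suite.
#'
#' @inheritParams g_function
#' @return A tibble with columns `factor`, `first_order`, `total`.
#' @export
g_function_analytic_indices <- function(a) {
  check_importance(a)
  v <- (1 / 3) / (1 + a)^2
  denom <- prod(1 + v) - 1
  s <- v / denom
  t <- 1 - (vapply(seq_along(v), function(i) prod(1 + v[-i]), numeric(1)) - 1) / denom
  tibble(
    factor = paste0("x", seq_along(a)),
    first_order = s,
    total = t
  )
}
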