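#' Logarithmic psychophysical law (Bernoulli principle)
#'
#' Sensation magnitude produced by a stimulus under the logarithmic
#' law \eqn{\gamma = b \log(\beta / \alpha)}, where `b` is a
#' proportionality constant and `alpha` a threshold stimulus. In the
#' Wnt time-course setting the "stimulus" is a fold change and the
#' deviation of interest is the relative increment
#' \eqn{\Delta\beta/\beta} that Weber's law keeps constant for a just
#' noticeable sensation increment. Natural logarithms are used
#' throughout; the Weber ratio identity below is base-invariant.
#'
#' @param beta Stimulus magnitude, positive.
#' @param alpha Threshold stimulus, positive, same units as `beta`.
#' @param b Proportionality constant.
#' @return Sensation magnitude `gamma`.
#' @seealso [sensation_increment()], [weber_ratio_from_increment()]
#' @export
bernoulli_sensation <- function(beta, alpha, b = 1) {
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop_domain("`beta` must be positive.")
  }
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop_domain("`alpha` must be positive.")
  }
  b * log(beta / alpha)
}

#' Sensation increment for a stimulus increment
#'
#' The increment \eqn{\Delta\gamma = b \log(1 + \Delta\beta/\beta)}
#' obtained by differencing the logarithmic law at `beta + delta_beta`
#' and `beta`; the threshold `alpha` cancels, so the increment depends
#' on the stimulus only through the relative increment
#' \eqn{\Delta\beta/\beta}.
#'
#' @param beta Stimulus magnitude, positive.
#' @param delta_beta Stimulus increment; `beta + delta_beta` must be
#'   positive.
#' @param b Proportionality constant.
#' @return Sensation increment `delta_gamma`.
#' @export
sensation_increment <- function(beta, delta_beta, b = 1) {
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop_domain("`beta` must be positive.")
  }
  if (any(!is.finite(delta_beta)) || any(beta + delta_beta <= 0)) {
    stop_domain("`beta + delta_beta` must be positive.")
  }
  b * log(1 + delta_beta / beta)
}

#' Weber ratio recovered from a sensation increment
#'
#' Inverts the logarithmic law: \eqn{k_r = (e^{\Delta\gamma})^{1/b} - 1},
#' which recovers the relative stimulus increment
#' \eqn{k_r = \Delta\beta/\beta}. Composing with
#' [sensation_increment()] is an exact algebraic round trip.
#'
#' @param delta_gamma Sensation increment.
#' @param b Proportionality constant, non-zero.
#' @return The Weber ratio `k_r`.
#' @examples
#' # round trip recovers delta_beta / beta exactly
#' weber_ratio_from_increment(sensation_increment(2, 0.5, b = 3), b = 3)
#' @export
weber_ratio_from_increment <- function(delta_gamma, b = 1) {
  if (any(!is.finite(b)) || any(b == 0)) {
    stop_domain("`b` must be non-zero.")
  }
  exp(delta_gamma / b) - 1
}

#' Tabulate the psychophysical quantities for stimulus/increment pairs
#'
#' Convenience wrapper returning all derived quantities of the
#' logarithmic law for vectors of stimuli and increments.
#'
#' @inheritParams sensation_increment
#' @inheritParams bernoulli_sensation
#' @return A tibble with columns `beta`, `delta_beta`, `b`, `alpha`,
#'   `gamma`, `delta_gamma` and the Weber ratio `k_r`.
#' @export
weber_record <- function(beta, delta_beta, b = 1, alpha = 1) {
  gamma <- bernoulli_sensation(beta, alpha, b)
  dg <- sensation_increment(beta, delta_beta, b)
  tibble(
    beta = beta, delta_beta = delta_beta, b = b, alpha = alpha,
    gamma = gamma, delta_gamma = dg,
    k_r = weber_ratio_from_increment(dg, b)
  )
}
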