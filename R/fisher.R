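#' Fisher information of a decay rate from one noisy measurement
#'
#' For the single-exponential decay y = i0 * exp(-rate * t) with known
#' basal intensity `i0` and additive Gaussian noise of SD `sigma`, the
#' Fisher information about the rate carried by one measurement at time
#' `t` is (dy/drate)^2 / sigma^2 = (i0 * t * exp(-rate * t) / sigma)^2.
#' It is maximal at rate * t = 1, which is why the most informative
#' saturation duration of a CEST measurement tracks 1/R1rho.
#'
#' @param t Measurement time(s), s.
#' @param rate Decay rate, s^-1.
#' @param i0 Known basal intensity.
#' @param sigma Noise SD.
#' @return Fisher information (same length as `t`).
#' @examples
#' topt <- optimal_saturation_time(2)
#' topt * 2  # = 1: the dimensionless optimum
#' @export
decay_rate_information <- function(t, rate, i0 = 1, sigma = 1) {
  stopifnot(rate > 0, i0 > 0, sigma > 0)
  (i0 * t * exp(-rate * t) / sigma)^2
}

#' @rdname decay_rate_information
#' @param t_max Upper end of the search interval (default 10/rate).
#' @return `optimal_saturation_time()`: the time maximizing the
#'   information, found numerically.
#' @export
optimal_saturation_time <- function(rate, t_max = 10 / rate) {
  stopifnot(rate > 0, t_max > 0)
  stats::optimize(decay_rate_information, c(0, t_max), rate = rate,
                  maximum = TRUE, tol = 1e-10)$maximum
}
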