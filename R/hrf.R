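#' Canonical double-gamma hemodynamic response function
#'
#' The standard difference-of-gammas kernel (response gamma with shape 6,
#' undershoot gamma with shape 16, both rate 1, undershoot ratio 1/6),
#' sampled on a 32 s support and normalized to unit peak. The peak falls at
#' about 5 s and the undershoot around 15 s.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param duration Kernel support in seconds.
#' @param peak_delay,undershoot_delay Gamma shape parameters of the response
#'   and undershoot components (rate 1, so the modes are at `peak_delay - 1`
#'   and `undershoot_delay - 1` seconds).
#' @param undershoot_ratio Relative amplitude of the undershoot component.
#' @return Numeric vector of kernel values at `seq(0, duration, by = dt)`,
#'   with max equal to 1.
#' @export
double_gamma_hrf <- function(dt, duration = 32,
                             peak_delay = 6, undershoot_delay = 16,
                             undershoot_ratio = 1 / 6) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h / max(h)
}
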