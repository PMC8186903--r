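#' Canonical double-gamma haemodynamic response function
#'
#' Evaluates the canonical double-gamma HRF (response peak at 6 s,
#' undershoot peak at 16 s, peak-to-undershoot ratio 6) at the given
#' times.  The kernel is the community-default shape consistent with an
#' early haemodynamic delay of a few seconds.
#'
#' @param t Numeric vector of times in seconds (values < 0 give 0).
#' @return Numeric vector of HRF values, unnormalised.
#' @export
#' @examples
#' t <- seq(0, 32, by = 0.5)
#' h <- hrf_double_gamma(t)
#' t[which.max(h)]  # ~6 s
hrf_double_gamma <- function(t) {
  stopifnot(is.numeric(t))
  h <- ifelse(t < 0, 0, stats::dgamma(t, shape = 6, rate = 1) -
                stats::dgamma(t, shape = 16, rate = 1) / 6)
  h
}

#' HRF kernel sampled at the repetition time
#'
#' Returns the double-gamma HRF sampled every `tr_s` seconds over
#' `duration_s`, normalised to peak 1 so that convolving a neural drive
#' expressed in % signal keeps its units.
#'
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @param duration_s Kernel support in seconds (default 32).
#' @return Numeric vector, first sample at t = 0.
#' @export
hrf_kernel <- function(tr_s, duration_s = 32) {
  stopifnot(tr_s > 0, duration_s > tr_s)
  t <- seq(0, duration_s, by = tr_s)
  h <- hrf_double_gamma(t)
  h / max(h)
}

#' Phase delay of the HRF at a given frequency
#'
#' The group delay that the canonical HRF imposes on a sinusoid of the
#' given frequency, in seconds.  For a travelling-wave design with cycle
#' period `cycle_s`, this is the lag by which the fundamental of a
#' single (non mirror-averaged) run trails the stimulus.
#'
#' @param cycle_s Cycle period in seconds (frequency = 1/cycle_s).
#' @param dt Integration step in seconds.
#' @return Delay in seconds.
#' @export
#' @examples
#' hrf_phase_delay(25.6)  # ~5.6 s
hrf_phase_delay <- function(cycle_s, dt = 0.01) {
  stopifnot(cycle_s > 0)
  t <- seq(0, 40, by = dt)
  h <- hrf_double_gamma(t)
  f <- 1 / cycle_s
  H <- sum(h * exp(-2i * pi * f * t)) * dt
  as.numeric(-Arg(H) / (2 * pi * f))
}

## discrete causal convolution with an HRF kernel, truncated to input length
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  y <- stats::convolve(c(x, rep(0, length(kernel))), rev(kernel),
                       type = "open")
  y[seq_len(n)]
}
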