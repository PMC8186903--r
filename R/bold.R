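#' Simulate surface-sampled BOLD from a tuned cortical patch
#'
#' Forward model for every vertex of a [make_cortex_patch()] patch under
#' a stimulus design: the neural drive at volume t is
#' `gain * exp(-(s(t) - x)^2 / (2 sigma^2))` (s(t) the active
#' stimulus-space position, x the vertex's preferred position, in %
#' signal), convolved with the canonical double-gamma HRF sampled at the
#' TR, scaled by the baseline, plus optionally AR(1)-correlated Gaussian
#' noise.
#'
#' @param patch A `cortex_patch`.
#' @param design A [stimulus_design] (phase, block, or rest).
#' @param noise_sd Noise standard deviation in % signal (>= 0).
#' @param ar1_coef AR(1) coefficient of the noise in \[0, 1).
#' @param seed Integer seed.
#' @return A [somato_ts], volumes x vertices, in raw intensity units.
#' @export
#' @examples
#' p <- make_cortex_patch(c(4, 4), seed = 1)
#' d <- make_phase_design("forward", n_cycles = 2)
#' ts <- simulate_bold(p, d, noise_sd = 0.5, seed = 2)
simulate_bold <- function(patch, design, noise_sd = 0.5, ar1_coef = 0,
                          seed = 1) {
  stopifnot(inherits(patch, "cortex_patch"), is_stimulus_design(design))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (ar1_coef < 0 || ar1_coef >= 1) stop("ar1_coef must be in [0, 1)")
  local_rng(seed)
  n_vol <- design$n_volumes
  n_vert <- nrow(patch$vertices)
  s <- design$stimulus_position
  kern <- hrf_kernel(design$tr_s)
  y <- matrix(0, n_vol, n_vert)
  for (v in seq_len(n_vert)) {
    drive <- ifelse(is.na(s), 0,
                    patch$gain[v] *
                      exp(-(s - patch$preferred_position[v])^2 /
                            (2 * patch$tuning_sigma[v]^2)))
    resp <- convolve_hrf(drive, kern)        # % signal
    y[, v] <- patch$baseline[v] * (1 + resp / 100)
  }
  if (noise_sd > 0) {
    eps <- matrix(stats::rnorm(n_vol * n_vert), n_vol, n_vert)
    if (ar1_coef > 0) {
      for (t in 2:n_vol)
        eps[t, ] <- ar1_coef * eps[t - 1, ] +
          sqrt(1 - ar1_coef^2) * eps[t, ]
    }
    y <- y + sweep(eps, 2, patch$baseline * noise_sd / 100, `*`)
  }
  somato_ts(y, design$tr_s)
}

#' Simulate resting-state finger time series with a target correlation
#'
#' Draws `n_volumes` samples of an `n_fingers`-dimensional Gaussian with
#' the given correlation structure, emulating slow-fluctuation coupling
#' between finger representations at rest.  Sample correlations converge
#' to `corr_matrix` as the series lengthens.
#'
#' @param n_fingers Number of finger series (default 5).
#' @param corr_matrix Symmetric positive semi-definite correlation
#'   matrix with unit diagonal (default identity).
#' @param n_volumes Series length in volumes (default 150).
#' @param tr_s Repetition time in seconds (default 2).
#' @param seed Integer seed.
#' @return A [somato_ts], volumes x fingers.
#' @export
simulate_resting <- function(n_fingers = 5, corr_matrix = diag(n_fingers),
                             n_volumes = 150, tr_s = 2, seed = 1) {
  corr_matrix <- as.matrix(corr_matrix)
  stopifnot(nrow(corr_matrix) == n_fingers,
            ncol(corr_matrix) == n_fingers)
  if (max(abs(corr_matrix - t(corr_matrix))) > 1e-8)
    stop("corr_matrix must be symmetric")
  if (max(abs(diag(corr_matrix) - 1)) > 1e-8)
    stop("corr_matrix must have unit diagonal")
  ev <- eigen(corr_matrix, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("corr_matrix must be positive semi-definite")
  local_rng(seed)
  root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_fingers) %*%
    t(ev$vectors)
  z <- matrix(stats::rnorm(n_volumes * n_fingers), n_volumes, n_fingers)
  y <- z %*% root
  colnames(y) <- digit_labels()[seq_len(n_fingers)]
  somato_ts(y, tr_s)
}
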