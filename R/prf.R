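#' Predict a BOLD series from 1D Gaussian pRF parameters
#'
#' The neural drive at volume t is
#' `gain * exp(-(s(t) - x)^2 / (2 sigma^2))` with s(t) the active
#' stimulus-space position (0 when nothing is stimulated); the
#' prediction is the baseline plus the HRF-convolved drive.
#'
#' @param x pRF centre in stimulus-space units, in \[-12.5, 12.5\].
#' @param sigma pRF width (Gaussian SD) in units, in \[0.5, 25\].
#' @param gain Response gain in the units of the series.
#' @param baseline Additive baseline.
#' @param design A [stimulus_design] with stimulus positions.
#' @param hrf HRF kernel sampled at the TR; `NULL` (default) uses the
#'   canonical double-gamma, `NA` skips convolution.
#' @return Numeric predicted series of length `design$n_volumes`.
#' @export
prf_predict <- function(x, sigma, gain, baseline, design, hrf = NULL) {
  stopifnot(is_stimulus_design(design))
  if (sigma < 0.5) stop("sigma below the minimal pRF width 0.5")
  s <- design$stimulus_position
  drive <- ifelse(is.na(s), 0, gain * exp(-(s - x)^2 / (2 * sigma^2)))
  if (length(hrf) == 1 && is.na(hrf)) return(baseline + drive)
  if (is.null(hrf)) hrf <- hrf_kernel(design$tr_s)
  baseline + convolve_hrf(drive, hrf)
}

## five HRF-convolved digit boxcar regressors for a design
digit_regressors <- function(design, hrf = NULL) {
  stopifnot(is_stimulus_design(design))
  if (is.null(hrf)) hrf <- hrf_kernel(design$tr_s)
  dig <- digits_per_volume(design$onsets, design$n_volumes, design$tr_s)
  X <- vapply(1:5, function(d) convolve_hrf(as.numeric(dig == d), hrf),
              numeric(design$n_volumes))
  colnames(X) <- digit_labels()
  X
}

#' Screen vertices for task responsiveness
#'
#' Ordinary least squares of every vertex series on the five
#' HRF-convolved digit regressors plus an intercept, with a per-vertex
#' omnibus F-test against the intercept-only model.  Vertices with
#' p < `alpha` pass; constant (zero-variance) series are excluded.
#'
#' @param ts A [somato_ts].
#' @param design A block or phase [stimulus_design].
#' @param alpha Significance level (default 0.05, uncorrected).
#' @return Logical mask with attribute `p_values`.
#' @export
screen_vertices <- function(ts, design, alpha = 0.05) {
  ts <- as_somato_ts(ts)
  X <- cbind(1, digit_regressors(design))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient digit design")
  y <- ts$data
  n <- nrow(y); p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  rss1 <- colSums(as.matrix(fit$residuals)^2)
  rss0 <- colSums(sweep(y, 2, colMeans(y))^2)
  df1 <- p - 1; df2 <- n - p
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  const <- rss0 < 1e-12
  pval[const] <- NA_real_
  mask <- !is.na(pval) & pval < alpha
  attr(mask, "p_values") <- pval
  mask
}

## solve gain (>= 0) and baseline for a fixed pRF regressor, return fit
solve_gain_baseline <- function(r, y) {
  X <- cbind(1, r)
  b <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) c(NA, NA))
  if (anyNA(b) || b[2] < 0) {
    ## gain pinned at 0: baseline is the mean
    b <- c(mean(y), 0)
  }
  pred <- X %*% b
  list(baseline = b[1], gain = b[2], sse = sum((y - pred)^2))
}

#' Fit a 1D Gaussian pRF to one vertex series
#'
#' Coarse grid search over centre x and width sigma (gain and baseline
#' solved linearly at each candidate) followed by bounded L-BFGS-B
#' refinement of (x, sigma).  Bounds follow the somatosensory stimulus
#' space: x in \[-12.5, 12.5\], sigma in \[0.5, 25\].
#'
#' @param y Numeric series for one vertex.
#' @param design A [stimulus_design].
#' @param x_bounds,sigma_bounds Parameter bounds.
#' @param n_grid Grid resolution `c(n_x, n_sigma)` (default 21 x 12).
#' @param hrf Optional HRF kernel (default canonical).
#' @return A `prf_fit` list: `x`, `sigma`, `gain`, `baseline`,
#'   `goodness` (variance explained, clipped to \[0, 1\]), `converged`,
#'   `assigned_digit` (from the centre's 5-unit interval).
#' @export
fit_prf <- function(y, design, x_bounds = c(-12.5, 12.5),
                    sigma_bounds = c(0.5, 25), n_grid = c(21, 12),
                    hrf = NULL) {
  stopifnot(is_stimulus_design(design), length(y) == design$n_volumes)
  if (is.null(hrf)) hrf <- hrf_kernel(design$tr_s)
  s <- design$stimulus_position
  drive_of <- function(x, sigma)
    ifelse(is.na(s), 0, exp(-(s - x)^2 / (2 * sigma^2)))
  reg_of <- function(x, sigma) convolve_hrf(drive_of(x, sigma), hrf)
  obj <- function(par) solve_gain_baseline(reg_of(par[1], par[2]), y)$sse
  xs <- seq(x_bounds[1], x_bounds[2], length.out = n_grid[1])
  sigmas <- exp(seq(log(sigma_bounds[1]), log(sigma_bounds[2]),
                    length.out = n_grid[2]))
  grid <- as.matrix(expand.grid(x = xs, sigma = sigmas))
  sse <- apply(grid, 1, obj)
  best <- grid[which.min(sse), ]
  opt <- tryCatch(
    stats::optim(best, obj, method = "L-BFGS-B",
                 lower = c(x_bounds[1], sigma_bounds[1]),
                 upper = c(x_bounds[2], sigma_bounds[2])),
    error = function(e) NULL)
  if (is.null(opt) || opt$value > min(sse)) {
    par <- best; converged <- FALSE
  } else {
    par <- opt$par; converged <- opt$convergence == 0
  }
  gb <- solve_gain_baseline(reg_of(par[1], par[2]), y)
  sst <- sum((y - mean(y))^2)
  goodness <- if (sst > 0) max(0, min(1, 1 - gb$sse / sst)) else 0
  structure(
    list(x = unname(par[1]), sigma = unname(par[2]), gain = gb$gain,
         baseline = gb$baseline, goodness = goodness,
         converged = converged,
         assigned_digit = position_to_digit(unname(par[1]))),
    class = "prf_fit")
}

#' Fit pRFs to all screened vertices of a run
#'
#' Convenience wrapper: screens vertices with [screen_vertices()] and
#' fits [fit_prf()] to each passing vertex.
#'
#' @param ts A [somato_ts].
#' @param design A [stimulus_design].
#' @param alpha Screening level (default 0.05).
#' @param ... Passed to [fit_prf()].
#' @return Data frame with one row per screened vertex: `vertex`, `x`,
#'   `sigma`, `gain`, `baseline`, `goodness`, `converged`, `digit`.
#' @export
fit_prf_map <- function(ts, design, alpha = 0.05, ...) {
  ts <- as_somato_ts(ts)
  mask <- screen_vertices(ts, design, alpha)
  idx <- which(mask)
  rows <- lapply(idx, function(v) {
    f <- fit_prf(ts$data[, v], design, ...)
    data.frame(vertex = v, x = f$x, sigma = f$sigma, gain = f$gain,
               baseline = f$baseline, goodness = f$goodness,
               converged = f$converged, digit = f$assigned_digit)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-digit pRF size summaries
#'
#' Means and SDs of fitted pRF widths per digit over fits retained at a
#' goodness-of-fit threshold.  Digits with no retained fit are reported
#' as missing (NA), never as zero.
#'
#' @param fits Data frame from [fit_prf_map()] (columns `sigma`,
#'   `goodness`, `digit`).
#' @param good_threshold Minimum variance explained to retain a fit
#'   (default 0.2).
#' @return Data frame with `digit`, `n`, `mean_sigma`, `sd_sigma`,
#'   `missing`.
#' @export
summarize_prf <- function(fits, good_threshold = 0.2) {
  stopifnot(all(c("sigma", "goodness", "digit") %in% names(fits)))
  kept <- fits[fits$goodness >= good_threshold, ]
  out <- do.call(rbind, lapply(1:5, function(d) {
    s <- kept$sigma[kept$digit == d]
    data.frame(digit = d, n = length(s),
               mean_sigma = if (length(s)) mean(s) else NA_real_,
               sd_sigma = if (length(s) > 1) stats::sd(s) else NA_real_,
               missing = length(s) == 0)
  }))
  out
}
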