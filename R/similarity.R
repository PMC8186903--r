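#' Finger beta and contrast maps from a blocked run
#'
#' Ordinary least squares of every vertex on five HRF-convolved digit
#' regressors plus an intercept, then per digit the contrast
#' `4 x own - 1 x each other` (e.g. `[4 -1 -1 -1 -1]` for D1).  The
#' contrast weights sum to zero, so adding a constant to a series
#' leaves the contrasts unchanged.
#'
#' @param ts A [somato_ts].
#' @param design A block [stimulus_design].
#' @param what `"contrast"` (default) or `"beta"` (raw digit betas).
#' @return Vertices x 5 matrix (columns D1-D5).
#' @export
finger_betas <- function(ts, design, what = c("contrast", "beta")) {
  what <- match.arg(what)
  ts <- as_somato_ts(ts)
  X <- cbind(1, digit_regressors(design))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient digit design")
  B <- stats::lm.fit(X, ts$data)$coefficients[-1, , drop = FALSE]  # 5 x V
  if (what == "beta") return(t(B))
  C <- matrix(-1, 5, 5); diag(C) <- 4
  out <- t(C %*% B)
  colnames(out) <- digit_labels()
  out
}

#' Between-run representational similarity matrix
#'
#' Entry (i, j) is the Pearson correlation over masked vertices between
#' the run-1 digit-i map and the run-2 digit-j map; optionally Fisher
#' z-transformed (atanh) for averaging across subjects.
#'
#' @param betas_run1,betas_run2 Vertices x 5 matrices from
#'   [finger_betas()].
#' @param mask Optional logical vertex mask.
#' @param fisher_z Apply atanh to the correlations (default FALSE).
#' @return 5 x 5 matrix (rows = run-1 digits, cols = run-2 digits).
#'   Constant maps yield NA entries with a warning.
#' @export
between_run_similarity <- function(betas_run1, betas_run2, mask = NULL,
                                   fisher_z = FALSE) {
  stopifnot(ncol(betas_run1) == 5, ncol(betas_run2) == 5,
            nrow(betas_run1) == nrow(betas_run2))
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(betas_run1))
    betas_run1 <- betas_run1[mask, , drop = FALSE]
    betas_run2 <- betas_run2[mask, , drop = FALSE]
  }
  sd1 <- apply(betas_run1, 2, stats::sd)
  sd2 <- apply(betas_run2, 2, stats::sd)
  if (any(sd1 == 0) || any(sd2 == 0))
    warning("constant beta map(s): undefined correlations set to NA")
  r <- suppressWarnings(stats::cor(betas_run1, betas_run2))
  r[is.nan(r)] <- NA_real_
  if (fisher_z) r <- atanh(r)
  dimnames(r) <- list(digit_labels(), digit_labels())
  r
}

#' Neighbour summary of a 5 x 5 similarity matrix
#'
#' Mean similarity per digit-neighbour distance: N0 averages the 5
#' diagonal (same-finger) entries; Nk (k = 1..4) averages all ordered
#' entry pairs with |i - j| = k — 8, 6, 4 and 2 entries respectively
#' (both off-diagonal wings).  Set `ordered = FALSE` to average the
#' upper wing only (4, 3, 2, 1 entries); for a symmetric matrix the two
#' conventions agree.
#'
#' @param m 5 x 5 similarity matrix.
#' @param ordered Use both wings (default TRUE).
#' @return Named numeric vector N0..N4.
#' @export
neighbor_summary <- function(m, ordered = TRUE) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == 5))
  dist <- abs(outer(1:5, 1:5, `-`))
  if (!ordered) dist[lower.tri(dist)] <- -1L
  out <- vapply(0:4, function(k) mean(m[dist == k]), numeric(1))
  names(out) <- paste0("N", 0:4)
  out
}

#' Lagged cross-correlation of two resting-state series
#'
#' Pearson correlation of the overlapping segments of two series at
#' every integer lag in `[-max_lag_trs, +max_lag_trs]` (positive lag:
#' the second series is delayed), with the peak lag reported.
#'
#' @param series_i,series_j Numeric series of equal length.
#' @param max_lag_trs Maximum lag in TRs (default 130).
#' @return List with `lags`, `r` (correlation per lag), `peak_lag`,
#'   `peak_r`, `zero_lag_r`.
#' @export
resting_xcorr <- function(series_i, series_j, max_lag_trs = 130) {
  n <- length(series_i)
  stopifnot(length(series_j) == n, n > max_lag_trs + 2)
  if (stats::sd(series_i) == 0 || stats::sd(series_j) == 0)
    stop("constant series: cross-correlation undefined")
  lags <- seq(-max_lag_trs, max_lag_trs)
  r <- vapply(lags, function(L) {
    if (L >= 0) {
      a <- series_i[seq_len(n - L)]
      b <- series_j[seq_len(n - L) + L]
    } else {
      a <- series_i[seq_len(n + L) - L]
      b <- series_j[seq_len(n + L)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  k <- which.max(abs(r))
  list(lags = lags, r = r, peak_lag = lags[k], peak_r = r[k],
       zero_lag_r = r[lags == 0])
}
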