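#' Average mirror-symmetric travelling-wave runs
#'
#' The reverse-order run is reversed in time scan-by-scan (making its
#' stimulus sequence identical to the forward run), circularly shifted
#' forward by `shift_trs` volumes to compensate for hemodynamic delay,
#' and averaged timepoint-wise with the forward run.  Note that time
#' reversal flips the sign of the hemodynamic delay, so the averaged
#' series retains a residual delay of `shift_trs * tr / 2` seconds (see
#' [assign_digits_from_phase()]).
#'
#' @param forward_ts,reverse_ts [somato_ts] objects of equal dimensions
#'   and TR.
#' @param shift_trs Shift in volumes (default 2, i.e. 4 s at TR 2 s).
#' @return A [somato_ts] of the averaged run.
#' @export
average_mirror_runs <- function(forward_ts, reverse_ts, shift_trs = 2) {
  forward_ts <- as_somato_ts(forward_ts)
  reverse_ts <- as_somato_ts(reverse_ts)
  if (!all(dim(forward_ts$data) == dim(reverse_ts$data)))
    stop("forward and reverse runs must have identical dimensions")
  if (forward_ts$tr_s != reverse_ts$tr_s)
    stop("forward and reverse runs must share the TR")
  n <- nrow(forward_ts$data)
  rev_flipped <- reverse_ts$data[n:1, , drop = FALSE]
  idx <- ((seq_len(n) - 1 - shift_trs) %% n) + 1  # circular shift forward
  rev_shifted <- rev_flipped[idx, , drop = FALSE]
  somato_ts((forward_ts$data + rev_shifted) / 2, forward_ts$tr_s)
}

#' Stimulus-frequency Fourier statistics per vertex
#'
#' Discrete Fourier transform of each vertex time series; the signal is
#' the power at the stimulus frequency (bin `n_cycles`), the noise is
#' the mean power over all other admissible frequencies: bins at or
#' above `low_freq_cutoff_hz` up to the Nyquist limit, excluding the
#' stimulus bin and (by default) its 2nd and 3rd harmonics.  Reported
#' per vertex: the complex coefficient, response amplitude in % signal
#' (peak-to-peak relative to the series mean: DFT magnitude x 2 for the
#' negative frequency x 2 for peak-to-peak / N / baseline x 100), phase
#' in \[0, 2pi), the F-ratio signal/noise, and a p-value from an
#' F(2, 2 * n_noise_bins) reference distribution.
#'
#' @param ts A [somato_ts] (or matrix plus `tr_s`).
#' @param n_cycles Number of stimulation cycles in the run.
#' @param low_freq_cutoff_hz Frequencies below this are ignored as noise
#'   (default 0.005 Hz, drift/motion band).
#' @param exclude_harmonics Harmonic multiples of the stimulus bin to
#'   exclude from the noise set (default 2:3).
#' @param tr_s TR override when `ts` is a bare matrix.
#' @return A `fourier_map` data frame: `vertex`, `re`, `im`,
#'   `amplitude_percent`, `phase`, `f_ratio`, `p_value`, plus attributes
#'   `n_cycles`, `tr_s`, `n_noise_bins`.  Zero-variance vertices get
#'   `NA` F-ratio; noiseless periodic vertices get `Inf`.
#' @export
fourier_analyze <- function(ts, n_cycles, low_freq_cutoff_hz = 0.005,
                            exclude_harmonics = 2:3, tr_s = NULL) {
  ts <- as_somato_ts(ts, tr_s)
  x <- ts$data
  n <- nrow(x)
  stopifnot(n_cycles >= 1, n >= 2 * n_cycles)
  nyq <- floor(n / 2)
  freqs <- seq_len(nyq) / (n * ts$tr_s)
  admissible <- which(freqs >= low_freq_cutoff_hz - 1e-12)
  harm <- n_cycles * c(1, exclude_harmonics)
  noise_bins <- setdiff(admissible, harm[harm <= nyq])
  if (length(noise_bins) < 1) stop("no admissible noise bins")
  baseline <- colMeans(x)
  xc <- sweep(x, 2, baseline)
  ft <- stats::mvfft(xc)
  coef_sig <- ft[n_cycles + 1, ]
  p_sig <- Mod(coef_sig)^2
  p_noise <- colMeans(Mod(ft[noise_bins + 1, , drop = FALSE])^2)
  ## noise power below float roundoff of the signal counts as zero, so a
  ## noiseless periodic series is flagged infinite rather than huge-finite
  f_ratio <- ifelse(p_noise > p_sig * 1e-12, p_sig / p_noise,
                    ifelse(p_sig > 0, Inf, NA_real_))
  zero_var <- apply(xc, 2, function(v) all(abs(v) < 1e-12))
  f_ratio[zero_var] <- NA_real_
  n_noise <- length(noise_bins)
  p_value <- ifelse(is.finite(f_ratio),
                    stats::pf(f_ratio, 2, 2 * n_noise, lower.tail = FALSE),
                    ifelse(is.na(f_ratio), NA_real_, 0))
  amp_pct <- 2 * 2 * Mod(coef_sig) / n / baseline * 100
  ## response phase as the peak position within the cycle: a series
  ## peaking at cycle fraction f has DFT argument -2*pi*f, so negate
  phase <- (-Arg(coef_sig)) %% (2 * pi)
  out <- data.frame(vertex = seq_len(ncol(x)),
                    re = Re(coef_sig), im = Im(coef_sig),
                    amplitude_percent = amp_pct, phase = phase,
                    f_ratio = f_ratio, p_value = p_value)
  attr(out, "n_cycles") <- n_cycles
  attr(out, "tr_s") <- ts$tr_s
  attr(out, "n_volumes") <- n
  attr(out, "n_noise_bins") <- n_noise
  class(out) <- c("fourier_map", "data.frame")
  out
}

#' Assign digits from response phase
#'
#' Converts each vertex's cycle phase into a digit label by subtracting
#' the residual hemodynamic phase lag and binning the result into five
#' equal fifths of the cycle.  Increasing phase maps D1 to D5 for a
#' forward-order run and D5 to D1 for a reverse-order run.
#'
#' For mirror-averaged input (the default pipeline), time reversal of
#' the reverse run flips the sign of its hemodynamic delay, so after the
#' `shift_trs` compensation the average retains a residual lag of
#' exactly `shift_trs * tr / 2` seconds regardless of the true HRF
#' delay; the default `hemodynamic_lag_s = 2` matches the standard
#' 2-TR shift.  For a single (non-averaged) run, pass
#' `hemodynamic_lag_s = hrf_phase_delay(cycle_s)` instead.
#'
#' @param map A `fourier_map` from [fourier_analyze()].
#' @param direction `"forward"` or `"reverse"`.
#' @param hemodynamic_lag_s Residual hemodynamic lag in seconds removed
#'   before binning (default 2).
#' @return The map with an `assigned_digit` column (NA where the phase
#'   is undefined).
#' @export
assign_digits_from_phase <- function(map,
                                     direction = c("forward", "reverse"),
                                     hemodynamic_lag_s = 2) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "fourier_map"))
  n_cycles <- attr(map, "n_cycles")
  cycle_s <- attr(map, "n_volumes") * attr(map, "tr_s") / n_cycles
  lag_phase <- 2 * pi * hemodynamic_lag_s / cycle_s
  theta <- (map$phase - lag_phase) %% (2 * pi)
  bin <- pmin(5L, floor(theta / (2 * pi / 5)) + 1L)
  map$assigned_digit <- ifelse(is.na(map$f_ratio), NA_integer_,
                               if (direction == "forward") bin else 6L - bin)
  map
}

#' Cross-subject F-ratio of stimulus-frequency coefficients
#'
#' Scalar F-ratio measuring whether the complex stimulus-frequency
#' coefficients of n subjects share a common nonzero mean:
#' `(xav^2 + yav^2)` divided by
#' `((sum((x - xav)^2) + sum((y - yav)^2)) / n) / (2n - 2)`, where x and
#' y are the real and imaginary parts and xav, yav their means.
#'
#' @param coefficients Complex vector, one coefficient per subject.
#' @return The F-ratio; `Inf` when all subjects are identical and
#'   nonzero.
#' @export
cross_subject_f_ratio <- function(coefficients) {
  coefficients <- as.complex(coefficients)
  n <- length(coefficients)
  if (n < 2) stop("need at least 2 subjects")
  x <- Re(coefficients); y <- Im(coefficients)
  xav <- mean(x); yav <- mean(y)
  num <- xav^2 + yav^2
  denom <- (sum((x - xav)^2) / n + sum((y - yav)^2) / n) / (2 * n - 2)
  if (denom == 0) {
    if (num == 0) return(NaN)
    return(Inf)
  }
  num / denom
}

#' Dispersion index of map alignment
#'
#' Amplitude of the vector average divided by the average amplitude of
#' the individual vectors.  Equals 1 for perfectly phase-aligned
#' vectors regardless of their amplitudes, and 0 for vectors that cancel
#' out; it separates a group average driven by consistent small signals
#' from one driven by inconsistent large signals.
#'
#' @param coefficients Complex vector, one per subject.
#' @return Dispersion index in \[0, 1\]; `NaN` when all vectors are
#'   zero.
#' @export
#' @examples
#' dispersion_index(c(1 + 0i, 0 + 1i))  # sqrt(2)/2
dispersion_index <- function(coefficients) {
  coefficients <- as.complex(coefficients)
  if (length(coefficients) < 1) stop("need at least one vector")
  denom <- mean(Mod(coefficients))
  if (denom == 0) return(NaN)
  Mod(mean(coefficients)) / denom
}

#' Surface cluster filtering of significant vertices
#'
#' Keeps only those supra-threshold vertices (per-vertex p below
#' `p_threshold`) that belong to an edge-connected component of the mesh
#' whose summed vertex-wise area reaches `min_area_mm2`.
#'
#' @param p_values Per-vertex p-values (e.g. from [fourier_analyze()]).
#' @param patch A `cortex_patch` supplying mesh connectivity and areas.
#' @param p_threshold Pre-cluster threshold (default 0.01).
#' @param min_area_mm2 Minimum component surface area (default 14).
#' @return Logical mask over vertices.
#' @export
cluster_filter <- function(p_values, patch, p_threshold = 0.01,
                           min_area_mm2 = 14) {
  stopifnot(inherits(patch, "cortex_patch"),
            length(p_values) == nrow(patch$vertices))
  supra <- !is.na(p_values) & p_values < p_threshold
  if (!any(supra)) return(supra)
  areas <- vertex_areas(patch)
  g <- igraph::graph_from_edgelist(mesh_edges(patch$faces),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(patch$vertices) -
                                     igraph::vcount(g)))
  sub <- igraph::induced_subgraph(g, which(supra))
  comp <- igraph::components(sub)
  keep_comp <- which(vapply(seq_len(comp$no), function(k)
    sum(areas[which(supra)[comp$membership == k]]), numeric(1)) >=
      min_area_mm2)
  mask <- rep(FALSE, length(p_values))
  mask[which(supra)[comp$membership %in% keep_comp]] <- TRUE
  mask
}

#' Winner-take-all digit labelling
#'
#' Labels each masked vertex with the digit whose statistic map is
#' maximal there; exact ties go to the lowest digit index.
#'
#' @param finger_stat_maps Vertices x 5 matrix (or list of 5 vectors) of
#'   per-digit statistics.
#' @param mask Optional logical mask; unmasked vertices get NA.
#' @return Integer vector of digit labels (1-5 or NA).
#' @export
winner_take_all <- function(finger_stat_maps, mask = NULL) {
  if (is.list(finger_stat_maps))
    finger_stat_maps <- do.call(cbind, finger_stat_maps)
  stopifnot(ncol(finger_stat_maps) == 5)
  lab <- apply(finger_stat_maps, 1, which.max)  # which.max: first = lowest
  lab <- as.integer(lab)
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(finger_stat_maps))
    lab[!mask] <- NA_integer_
  }
  lab
}
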