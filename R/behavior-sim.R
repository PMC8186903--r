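#' Simulate a finger mislocalization session
#'
#' Draws reported digits for a five-alternative forced-choice finger
#' identification task from a row-stochastic confusion model: row i
#' gives the probability of each report when digit i is stimulated.
#' Each digit is stimulated `n_trials_per_digit` times (default 20, the
#' standard session length).
#'
#' @param confusion_probs 5 x 5 row-stochastic matrix.
#' @param n_trials_per_digit Trials per stimulated digit (default 20).
#' @param seed Integer seed.
#' @return A `behavioral_trials` data frame with columns
#'   `stimulated_digit`, `reported_digit`, `trial`.
#' @export
#' @examples
#' tr <- simulate_mislocalization(diag(5), seed = 1)
#' all(tr$reported_digit == tr$stimulated_digit)
simulate_mislocalization <- function(confusion_probs,
                                     n_trials_per_digit = 20, seed = 1) {
  confusion_probs <- as.matrix(confusion_probs)
  stopifnot(all(dim(confusion_probs) == 5), n_trials_per_digit >= 1)
  if (any(confusion_probs < 0))
    stop("confusion_probs must be non-negative")
  if (max(abs(rowSums(confusion_probs) - 1)) > 1e-6)
    stop("confusion_probs rows must each sum to 1")
  local_rng(seed)
  stim <- rep(1:5, each = n_trials_per_digit)
  stim <- stim[sample.int(length(stim))]
  rep_d <- vapply(stim, function(d)
    sample.int(5, 1, prob = confusion_probs[d, ]), integer(1))
  out <- data.frame(stimulated_digit = stim, reported_digit = rep_d,
                    trial = seq_along(stim))
  attr(out, "n_trials_per_digit") <- n_trials_per_digit
  class(out) <- c("behavioral_trials", "data.frame")
  out
}

#' Monofilament intensity ladder
#'
#' The discrete ladder of calibrated filament weights (in grams) used
#' for detection-threshold staircases, and its log-transformed levels
#' (log10 of force in units of 0.1 mg).
#'
#' @return Data frame with `weight_g` and `level` (log10 0.1 mg).
#' @export
monofilament_ladder <- function() {
  w <- c(0.008, 0.02, 0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0, 4.0, 6.0)
  data.frame(weight_g = w, level = log10(w * 1e4))
}

## 3-down/1-up single staircase on a discrete ladder; returns visited levels
run_one_staircase <- function(p_correct, start_idx, n_levels,
                              max_trials, window = 10) {
  idx <- start_idx
  track <- integer(0)
  n_down <- 0L
  converged <- FALSE
  for (t in seq_len(max_trials)) {
    track <- c(track, idx)
    correct <- stats::runif(1) < p_correct(idx)
    if (correct) {
      n_down <- n_down + 1L
      if (n_down == 3L) {
        idx <- max(1L, idx - 1L)
        n_down <- 0L
      }
    } else {
      idx <- min(n_levels, idx + 1L)
      n_down <- 0L
    }
    if (length(track) >= window) {
      recent <- track[(length(track) - window + 1):length(track)]
      if (stats::sd(recent) <= 1) { converged <- TRUE; break }
    }
  }
  list(track = track, converged = converged)
}

#' Simulate 3-down/1-up detection-threshold staircases
#'
#' Runs two interleaved (trial-alternating) 3-down/1-up staircases on
#' the discrete monofilament ladder against a simulated observer whose
#' probability of a correct response is a logistic function of the
#' log-transformed stimulus level.  A staircase stops once the standard
#' deviation of its recently visited levels is at most one ladder step;
#' its threshold estimate is the mean of those levels.  The 3-down/1-up
#' rule converges on the ~79.4% correct point of the observer
#' (0.5^(1/3)).
#'
#' @param observer_threshold Observer threshold on the level scale
#'   (log10 0.1 mg): the level at which p(correct) = 0.5.
#' @param psychometric_slope Logistic slope on the level scale; `Inf`
#'   gives a deterministic step observer.
#' @param start_weights_g Starting weights of the two staircases in
#'   grams (default 0.4 and 0.02, snapped to the ladder).
#' @param max_trials Per-staircase trial cap; a run hitting it is
#'   flagged `converged = FALSE`.
#' @param window Number of recent levels over which convergence is
#'   assessed.
#' @param seed Integer seed.
#' @return List with `threshold` (level-scale estimate, mean of the two
#'   staircases), `threshold_g` (back-transformed grams), `converged`,
#'   and per-staircase `tracks` (ladder levels visited).
#' @export
simulate_staircase <- function(observer_threshold, psychometric_slope = 8,
                               start_weights_g = c(0.4, 0.02),
                               max_trials = 200, window = 10, seed = 1) {
  stopifnot(length(start_weights_g) == 2, psychometric_slope > 0)
  local_rng(seed)
  lad <- monofilament_ladder()
  n_levels <- nrow(lad)
  p_correct <- function(idx) {
    if (is.infinite(psychometric_slope))
      as.numeric(lad$level[idx] >= observer_threshold)
    else
      stats::plogis(psychometric_slope *
                      (lad$level[idx] - observer_threshold))
  }
  start_idx <- vapply(start_weights_g, function(w)
    which.min(abs(lad$weight_g - w)), integer(1))
  ## interleaving: the two staircases alternate trial-by-trial; with a
  ## per-trial iid observer this is equivalent to running them in sequence
  runs <- lapply(start_idx, function(s0)
    run_one_staircase(p_correct, s0, n_levels, max_trials, window))
  est <- vapply(runs, function(r) {
    tr <- r$track
    recent <- tr[max(1, length(tr) - window + 1):length(tr)]
    mean(lad$level[recent])
  }, numeric(1))
  list(threshold = mean(est),
       threshold_g = 10^mean(est) / 1e4,
       converged = all(vapply(runs, `[[`, logical(1), "converged")),
       tracks = lapply(runs, function(r) lad$level[r$track]))
}

#' Simulate a two-point discrimination run
#'
#' Binary "two pins felt" responses drawn from a logistic psychometric
#' function of pin distance centred on the true threshold: p(two) = 0.5
#' at `true_threshold_mm`.  The default distances follow the 0.7-2.8 mm
#' ladder in steps of 0.3 mm, with 10 repetitions per pin condition.
#'
#' @param true_threshold_mm True 50% threshold in mm.
#' @param slope Logistic slope per mm; `Inf` gives a step observer.
#' @param pin_distances_mm Distances tested (mm).
#' @param n_per_distance Trials per distance (default 10).
#' @param seed Integer seed.
#' @return Data frame with `distance_mm` and `two_felt` (0/1).
#' @export
simulate_2pd <- function(true_threshold_mm, slope = 3,
                         pin_distances_mm = seq(0.7, 2.8, by = 0.3),
                         n_per_distance = 10, seed = 1) {
  stopifnot(all(pin_distances_mm > 0), n_per_distance >= 1,
            true_threshold_mm > 0, slope > 0)
  local_rng(seed)
  d <- rep(pin_distances_mm, each = n_per_distance)
  p <- if (is.infinite(slope)) as.numeric(d >= true_threshold_mm)
  else stats::plogis(slope * (d - true_threshold_mm))
  data.frame(distance_mm = d,
             two_felt = as.integer(stats::runif(length(d)) < p))
}
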