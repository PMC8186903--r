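#' Stimulus designs
#'
#' A `stimulus_design` describes the per-volume stimulation state of one
#' fMRI run: which finger (and hence which stimulus-space position) is
#' active at each volume.  Designs are built by [make_phase_design()]
#' (travelling wave), [make_block_design()] (blocked stimulation with
#' jittered pauses) and [make_rest_design()].
#'
#' @param x Object to test or print.
#' @name stimulus_design
NULL

new_stimulus_design <- function(kind, tr_s, n_volumes, onsets,
                                stimulus_position, n_cycles = NA_integer_) {
  structure(
    list(kind = kind, tr_s = tr_s, n_volumes = as.integer(n_volumes),
         onsets = onsets, stimulus_position = stimulus_position,
         n_cycles = n_cycles),
    class = "stimulus_design")
}

#' @rdname stimulus_design
#' @export
is_stimulus_design <- function(x) inherits(x, "stimulus_design")

#' @export
print.stimulus_design <- function(x, ...) {
  cat(sprintf("<stimulus_design> kind=%s, %d volumes, TR=%gs (%.1f s)\n",
              x$kind, x$n_volumes, x$tr_s, x$n_volumes * x$tr_s))
  if (!is.na(x$n_cycles)) cat(sprintf("  %d cycles\n", x$n_cycles))
  invisible(x)
}

## active digit per volume from an onset table (volume sampled at its onset
## time); 0 = no stimulation
digits_per_volume <- function(onsets, n_volumes, tr_s) {
  t0 <- (seq_len(n_volumes) - 1) * tr_s
  dig <- integer(n_volumes)
  for (k in seq_len(nrow(onsets))) {
    on <- onsets$onset[k]
    idx <- which(t0 >= on - 1e-9 & t0 < on + onsets$duration[k] - 1e-9)
    dig[idx] <- onsets$digit[k]
  }
  dig
}

#' Travelling-wave (phase-encoded) stimulus design
#'
#' Builds a periodic design in which the five fingertips are stimulated
#' in sequence, `finger_duration_s` each, for `n_cycles` cycles.  The
#' standard protocol (20 cycles of 25.6 s, 5.12 s per finger, TR 2 s)
#' yields a 256-volume run.  The reverse direction stimulates D5 to D1
#' and is the exact digit-order mirror of the forward run.
#'
#' @param direction `"forward"` (D1 to D5) or `"reverse"` (D5 to D1).
#' @param n_cycles Number of stimulation cycles (default 20).
#' @param finger_duration_s Stimulation time per finger in seconds
#'   (default 5.12).
#' @param tr_s Repetition time in seconds (default 2).
#' @return A [stimulus_design] with per-volume `stimulus_position`.
#' @export
#' @examples
#' d <- make_phase_design("forward")
#' d$n_volumes  # 256
make_phase_design <- function(direction = c("forward", "reverse"),
                              n_cycles = 20, finger_duration_s = 5.12,
                              tr_s = 2) {
  direction <- match.arg(direction)
  stopifnot(n_cycles >= 1, finger_duration_s > 0, tr_s > 0)
  total_s <- 5 * finger_duration_s * n_cycles
  n_vol <- total_s / tr_s
  if (abs(n_vol - round(n_vol)) > 1e-8)
    stop(sprintf(paste0("phase design of %d cycles x 5 x %g s is %g s, ",
                        "not divisible by tr_s = %g s"),
                 n_cycles, finger_duration_s, total_s, tr_s))
  n_vol <- as.integer(round(n_vol))
  order_d <- if (direction == "forward") 1:5 else 5:1
  digit_seq <- rep(rep(order_d, n_cycles))
  onsets <- data.frame(
    digit = digit_seq,
    onset = (seq_along(digit_seq) - 1) * finger_duration_s,
    duration = finger_duration_s)
  dig <- digits_per_volume(onsets, n_vol, tr_s)
  pos <- ifelse(dig == 0, NA_real_, digit_to_position(pmax(dig, 1)))
  kind <- if (direction == "forward") "phase_forward" else "phase_reverse"
  new_stimulus_design(kind, tr_s, n_vol, onsets, pos,
                      n_cycles = as.integer(n_cycles))
}

## pseudo-random digit order with no digit more than `max_run` consecutive
sample_digit_order <- function(n_reps, max_run = 2, max_tries = 1000) {
  pool_full <- rep(1:5, n_reps)
  for (try in seq_len(max_tries)) {
    ord <- pool_full[sample.int(length(pool_full))]
    r <- rle(ord)
    if (all(r$lengths <= max_run)) return(ord)
  }
  stop("could not find a digit order without >", max_run,
       " consecutive repeats after ", max_tries, " tries")
}

#' Blocked stimulus design with jittered pauses
#'
#' Each finger is stimulated `n_reps_per_digit` times for `stim_s`
#' seconds in a pseudo-random order with never more than two consecutive
#' stimulations of the same finger.  A fraction `p_short_pause` of the
#' trials (exactly, after rounding, and counterbalanced within each
#' finger) is followed by a short pause, the rest by a long pause.  The
#' standard protocol (10 reps, 70% 2-s / 30% 6-s pauses, 5.12-s
#' stimulation, TR 2 s) yields a 208-volume run.
#'
#' @param n_reps_per_digit Stimulations per finger (default 10).
#' @param p_short_pause Fraction of trials with the short pause
#'   (default 0.7).
#' @param short_s,long_s Pause durations in seconds (defaults 2 and 6).
#' @param stim_s Stimulation duration in seconds (default 5.12).
#' @param tr_s Repetition time in seconds (default 2).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return A [stimulus_design].
#' @export
#' @examples
#' d <- make_block_design(seed = 1)
#' d$n_volumes  # 208
make_block_design <- function(n_reps_per_digit = 10, p_short_pause = 0.7,
                              short_s = 2, long_s = 6, stim_s = 5.12,
                              tr_s = 2, seed = 1) {
  stopifnot(n_reps_per_digit >= 1, p_short_pause >= 0, p_short_pause <= 1,
            short_s >= 0, long_s >= 0, stim_s > 0, tr_s > 0)
  local_rng(seed)
  n_trials <- 5L * n_reps_per_digit
  n_short_per_digit <- round(p_short_pause * n_reps_per_digit)
  ord <- sample_digit_order(n_reps_per_digit, max_run = 2)
  ## counterbalance pause type within each digit: exactly n_short short
  ## pauses per digit, in shuffled positions
  pause <- numeric(n_trials)
  for (d in 1:5) {
    idx <- which(ord == d)
    short_idx <- idx[sample.int(length(idx))][seq_len(n_short_per_digit)]
    pause[idx] <- long_s
    pause[short_idx] <- short_s
  }
  onset <- cumsum(c(0, head(stim_s + pause, -1)))
  total_s <- sum(stim_s + pause)
  n_vol <- total_s / tr_s
  if (abs(n_vol - round(n_vol)) > 1e-8)
    stop(sprintf("block design duration %g s not divisible by tr_s = %g s",
                 total_s, tr_s))
  n_vol <- as.integer(round(n_vol))
  onsets <- data.frame(digit = ord, onset = onset, duration = stim_s)
  dig <- digits_per_volume(onsets, n_vol, tr_s)
  pos <- ifelse(dig == 0, NA_real_, digit_to_position(pmax(dig, 1)))
  new_stimulus_design("block", tr_s, n_vol, onsets, pos)
}

#' Resting-state design
#'
#' A run with no stimulation, by default 5 minutes at TR 2 s.
#'
#' @param n_volumes Number of volumes (default 150).
#' @param tr_s Repetition time in seconds (default 2).
#' @return A [stimulus_design] of kind `"rest"`.
#' @export
make_rest_design <- function(n_volumes = 150, tr_s = 2) {
  stopifnot(n_volumes >= 1, tr_s > 0)
  new_stimulus_design("rest", tr_s, n_volumes,
                      data.frame(digit = integer(), onset = numeric(),
                                 duration = numeric()),
                      rep(NA_real_, n_volumes))
}
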