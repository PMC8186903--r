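#' Confusion matrix from a mislocalization trial table
#'
#' Tabulates stimulated x reported digit counts.  Mislocalizations are
#' off-diagonal responses (another finger reported than stimulated);
#' the hit rate per digit is the diagonal count divided by that digit's
#' row total, with digits that were never confused recorded as plain
#' zeros.
#'
#' @param trials Data frame with `stimulated_digit` and
#'   `reported_digit` in 1..5 (e.g. from
#'   [simulate_mislocalization()]).
#' @return 5 x 5 integer matrix (rows = stimulated, cols = reported)
#'   with attributes `hit_rate` (per digit) and `n_mislocalizations`.
#' @export
confusion_from_trials <- function(trials) {
  stopifnot(nrow(trials) >= 1,
            all(trials$stimulated_digit %in% 1:5),
            all(trials$reported_digit %in% 1:5))
  m <- table(factor(trials$stimulated_digit, 1:5),
             factor(trials$reported_digit, 1:5))
  m <- matrix(as.integer(m), 5, 5,
              dimnames = list(stimulated = digit_labels(),
                              reported = digit_labels()))
  hit <- diag(m) / pmax(rowSums(m), 1)
  hit[rowSums(m) == 0] <- NA_real_
  attr(m, "hit_rate") <- hit
  attr(m, "n_mislocalizations") <- sum(m) - sum(diag(m))
  m
}

#' Observed neighbour counts of mislocalizations
#'
#' Groups off-diagonal confusion counts by the distance between the
#' stimulated and reported digit: a D2 stimulation reported as D4 is an
#' N2 mislocalization, reported as D5 an N3, and so on.
#'
#' @param conf 5 x 5 confusion matrix (rows = stimulated).
#' @param percent_of `"total"` (percentages of all mislocalizations)
#'   controls the `percent` column of the result.
#' @return Data frame with `neighbor` (1..4), `observed`, `percent`.
#' @export
neighbor_counts <- function(conf, percent_of = "total") {
  conf <- as.matrix(conf)
  stopifnot(all(dim(conf) == 5))
  dist <- abs(outer(1:5, 1:5, `-`))
  obs <- vapply(1:4, function(k) sum(conf[dist == k]), numeric(1))
  total <- sum(obs)
  data.frame(neighbor = 1:4, observed = obs,
             percent = if (total > 0) 100 * obs / total else rep(0, 4))
}

#' Neighbour-weighted chance expectation for mislocalizations
#'
#' Across the five stimulated digits there are 8 ordered
#' (stimulated, reported) pairs at neighbour distance 1, 6 at distance
#' 2, 4 at distance 3 and 2 at distance 4 (20 in all), so under
#' position-blind guessing a total of T mislocalizations splits as
#' T x (8, 6, 4, 2)/20.  Fractional expectations are retained for
#' testing; rounded values are reported for display.
#'
#' @param total_mislocalizations Total mislocalization count T.
#' @return Data frame with `neighbor`, `weight`, `expected`
#'   (fractional), `expected_rounded`.
#' @export
#' @examples
#' chance_expected(942)$expected_rounded[1]  # 377
chance_expected <- function(total_mislocalizations) {
  stopifnot(total_mislocalizations >= 0)
  w <- c(8, 6, 4, 2)
  e <- total_mislocalizations * w / sum(w)
  data.frame(neighbor = 1:4, weight = w, expected = e,
             expected_rounded = round(e))
}

#' Count ordered digit pairs at each neighbour distance
#'
#' Enumerates ordered (stimulated, reported) pairs among D1-D5 at
#' neighbour distance k; the counts (8, 6, 4, 2) are the chance-model
#' weights of [chance_expected()].
#'
#' @return Named integer vector for distances 1..4.
#' @export
neighbor_pair_counts <- function() {
  dist <- abs(outer(1:5, 1:5, `-`))
  out <- vapply(1:4, function(k) sum(dist == k), integer(1))
  names(out) <- paste0("N", 1:4)
  out
}

#' G-test of goodness of fit
#'
#' Log-likelihood-ratio test `G = 2 sum O ln(O/E)` with zero observed
#' cells contributing 0, df = cells - 1, and a chi-squared reference
#' distribution.
#'
#' @param observed,expected Non-negative count vectors of equal length;
#'   totals must match to tolerance and all expected cells be positive.
#' @return List with `G`, `df`, `p_value`.
#' @export
#' @examples
#' g_test(c(10, 6, 3, 1), c(8, 6, 4, 2))$G  # ~1.35
g_test <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), all(observed >= 0))
  if (any(expected <= 0)) stop("expected cells must be positive")
  if (abs(sum(observed) - sum(expected)) > 1e-6 * max(1, sum(expected)))
    stop("observed and expected totals differ")
  terms <- ifelse(observed == 0, 0, observed * log(observed / expected))
  G <- 2 * sum(terms)
  df <- length(observed) - 1
  list(G = G, df = df,
       p_value = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Holm-Bonferroni-corrected family of G-tests
#'
#' Runs [g_test()] for each observed/expected pair and applies the
#' Holm-Bonferroni step-down correction across the family.
#'
#' @param observed_list,expected_list Lists of count vectors.
#' @param alpha Family significance level (default 0.05).
#' @return Data frame with `G`, `df`, `p_value`, `p_holm`,
#'   `significant`.
#' @export
g_test_family <- function(observed_list, expected_list, alpha = 0.05) {
  stopifnot(length(observed_list) == length(expected_list))
  res <- Map(g_test, observed_list, expected_list)
  p <- vapply(res, `[[`, numeric(1), "p_value")
  p_holm <- stats::p.adjust(p, method = "holm")
  data.frame(G = vapply(res, `[[`, numeric(1), "G"),
             df = vapply(res, `[[`, numeric(1), "df"),
             p_value = p, p_holm = p_holm,
             significant = p_holm < alpha)
}

#' Signal-detection measures from a confusion matrix
#'
#' Per digit: hits are correct detections of that digit; false alarms
#' are reports of that digit when any other was stimulated.  The
#' log-linear correction (add 0.5 to each count, 1 to each denominator)
#' keeps rates strictly inside (0, 1) before the z-transform.
#' Sensitivity `d' = z(hit) - z(FA)`; bias
#' `beta = exp((z(FA)^2 - z(hit)^2) / 2)`.
#'
#' @param conf 5 x 5 confusion matrix (rows = stimulated).
#' @return Data frame per digit: `hits`, `n_signal`, `false_alarms`,
#'   `n_noise`, `hit_rate`, `fa_rate` (corrected), `dprime`, `beta`.
#' @export
sdt_measures <- function(conf) {
  conf <- as.matrix(conf)
  stopifnot(all(dim(conf) == 5), all(conf >= 0))
  hits <- diag(conf)
  n_signal <- rowSums(conf)
  false_alarms <- colSums(conf) - diag(conf)
  n_noise <- sum(conf) - n_signal
  hr <- (hits + 0.5) / (n_signal + 1)
  far <- (false_alarms + 0.5) / (n_noise + 1)
  zh <- stats::qnorm(hr); zf <- stats::qnorm(far)
  data.frame(digit = 1:5, hits = hits, n_signal = n_signal,
             false_alarms = false_alarms, n_noise = n_noise,
             hit_rate = hr, fa_rate = far,
             dprime = zh - zf, beta = exp((zf^2 - zh^2) / 2),
             row.names = NULL)
}

#' Two-point discrimination threshold from binary responses
#'
#' Maximum-likelihood binary logistic regression of "two felt"
#' responses on pin distance; the threshold is the distance at which
#' the fitted curve crosses 50%.
#'
#' @param distances_mm Pin distance per trial (mm).
#' @param responses Binary responses (1 = two felt).
#' @return List with `threshold_mm`, `slope` (per mm), `estimable`;
#'   non-estimable data (all-same responses, complete separation, or a
#'   non-positive slope) give `threshold_mm = NA` and
#'   `estimable = FALSE` with a warning.
#' @export
two_pd_threshold <- function(distances_mm, responses) {
  stopifnot(length(distances_mm) == length(responses),
            all(responses %in% 0:1))
  if (length(unique(distances_mm)) < 2 || length(unique(responses)) < 2) {
    warning("threshold not estimable: need variation in both ",
            "distances and responses")
    return(list(threshold_mm = NA_real_, slope = NA_real_,
                estimable = FALSE))
  }
  fit <- suppressWarnings(
    stats::glm(responses ~ distances_mm, family = stats::binomial()))
  b <- stats::coef(fit)
  separated <- !fit$converged || abs(b[2]) > 50
  if (separated) {
    ## step-like data: bracket the threshold between the highest
    ## all-zero and lowest all-one distance
    agg <- tapply(responses, distances_mm, mean)
    d <- as.numeric(names(agg))
    lo <- suppressWarnings(max(d[agg < 0.5]))
    hi <- suppressWarnings(min(d[agg >= 0.5]))
    if (is.finite(lo) && is.finite(hi))
      return(list(threshold_mm = (lo + hi) / 2, slope = Inf,
                  estimable = TRUE))
    warning("threshold not estimable: complete separation without bracket")
    return(list(threshold_mm = NA_real_, slope = NA_real_,
                estimable = FALSE))
  }
  if (b[2] <= 0) {
    warning("threshold not estimable: non-increasing psychometric fit")
    return(list(threshold_mm = NA_real_, slope = unname(b[2]),
                estimable = FALSE))
  }
  list(threshold_mm = unname(-b[1] / b[2]), slope = unname(b[2]),
       estimable = TRUE)
}

#' Average two-point thresholds over runs
#'
#' Fits [two_pd_threshold()] per run and averages the estimable
#' thresholds, the convention for multi-block testing sessions.
#'
#' @param runs List of data frames with `distance_mm` and `two_felt`.
#' @return List with `threshold_mm` (mean over estimable runs),
#'   `per_run`, `n_estimable`.
#' @export
two_pd_threshold_runs <- function(runs) {
  per_run <- vapply(runs, function(r)
    two_pd_threshold(r$distance_mm, r$two_felt)$threshold_mm, numeric(1))
  list(threshold_mm = mean(per_run, na.rm = TRUE), per_run = per_run,
       n_estimable = sum(!is.na(per_run)))
}
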