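test_that("confusion matrices tabulate trials with hit rates and zeros", {
  correct <- data.frame(stimulated_digit = rep(1:5, each = 20),
                        reported_digit = rep(1:5, each = 20),
                        trial = 1:100)
  conf <- confusion_from_trials(correct)
  expect_equal(unname(diag(conf)), rep(20L, 5))
  expect_equal(attr(conf, "n_mislocalizations"), 0L)
  expect_equal(unname(attr(conf, "hit_rate")), rep(1, 5))
  # one error per digit: hit rate 0.95
  one_err <- correct
  one_err$reported_digit[c(1, 21, 41, 61, 81)] <-
    c(2, 3, 4, 5, 4)
  c2 <- confusion_from_trials(one_err)
  expect_equal(unname(attr(c2, "hit_rate")), rep(0.95, 5))
  expect_equal(unname(rowSums(c2)), rep(20L, 5))
  expect_error(confusion_from_trials(correct[0, ]), "nrow")
})

test_that("neighbour counts group errors by digit distance", {
  # a D2 -> D4 error is an N2 mislocalization
  tr <- data.frame(stimulated_digit = 2, reported_digit = 4, trial = 1)
  nc <- neighbor_counts(confusion_from_trials(tr))
  expect_equal(nc$observed, c(0, 1, 0, 0))
  # all-correct: all zero
  allc <- data.frame(stimulated_digit = 1:5, reported_digit = 1:5,
                     trial = 1:5)
  expect_equal(neighbor_counts(confusion_from_trials(allc))$observed,
               rep(0, 4))
  # one error in every off-diagonal cell: counts are the pair counts
  m <- matrix(1, 5, 5); diag(m) <- 0
  expect_equal(neighbor_counts(m)$observed, c(8, 6, 4, 2))
})

test_that("chance model splits totals 8:6:4:2 and conserves them", {
  ce <- chance_expected(942)
  expect_equal(ce$expected[1], 376.8)
  expect_equal(ce$expected_rounded[1], 377)
  expect_equal(sum(ce$expected), 942)
  expect_equal(chance_expected(20)$expected, c(8, 6, 4, 2))
  expect_equal(chance_expected(0)$expected, rep(0, 4))
  expect_equal(unname(neighbor_pair_counts()), c(8L, 6L, 4L, 2L))
})

test_that("G-test matches direct evaluation, including exhaustive small tables", {
  expect_equal(g_test(c(8, 6, 4, 2), c(8, 6, 4, 2))$G, 0)
  g <- g_test(c(10, 6, 3, 1), c(8, 6, 4, 2))
  expect_equal(g$G, 1.3505, tolerance = 1e-4)
  expect_equal(g$df, 3)  # 4 neighbour classes
  # exhaustive oracle over all 4-cell tables with total 12
  direct_g <- function(o, e) {
    keep <- o > 0
    2 * sum(o[keep] * log(o[keep] / e[keep]))
  }
  tot <- 12
  e <- tot * c(8, 6, 4, 2) / 20
  for (a in 0:tot) for (b in 0:(tot - a)) for (cc in 0:(tot - a - b)) {
    o <- c(a, b, cc, tot - a - b - cc)
    got <- g_test(o, e)
    expect_equal(got$G, direct_g(o, e), tolerance = 1e-12)
    expect_equal(got$p_value,
                 stats::pchisq(direct_g(o, e), 3, lower.tail = FALSE))
  }
  expect_error(g_test(c(1, 2), c(1, 1)), "totals differ")
  expect_error(g_test(c(1, 0), c(1, 0)), "positive")
})

test_that("Holm correction is applied across a G-test family", {
  obs <- list(c(16, 2, 1, 1), c(9, 6, 3, 2), c(8, 6, 4, 2))
  exp_ <- lapply(obs, function(o) sum(o) * c(8, 6, 4, 2) / 20)
  fam <- g_test_family(obs, exp_)
  expect_equal(fam$p_holm,
               stats::p.adjust(fam$p_value, method = "holm"))
  expect_true(fam$significant[1])
  expect_false(fam$significant[3])
})

test_that("SDT measures follow the log-linear-corrected formulas", {
  # uniform confusion: raw hit and false-alarm rates are equal (0.2), so
  # d' sits near 0 and beta near 1 (the correction's unequal
  # denominators leave a small residual); formulas hold exactly
  m <- matrix(4, 5, 5)
  s <- sdt_measures(m)
  expect_lt(max(abs(s$dprime)), 0.05)
  expect_lt(max(abs(s$beta - 1)), 0.05)
  expect_equal(s$hit_rate, (diag(m) + 0.5) / (rowSums(m) + 1))
  expect_equal(s$dprime,
               stats::qnorm(s$hit_rate) - stats::qnorm(s$fa_rate),
               tolerance = 1e-12)
  expect_equal(s$beta,
               exp((stats::qnorm(s$fa_rate)^2 -
                      stats::qnorm(s$hit_rate)^2) / 2),
               tolerance = 1e-12)
  # rates at z = +/-1 give d' = 2, beta = 1 (quantile oracle);
  # build counts whose corrected rates hit pnorm(1) and pnorm(-1)
  n_sig <- 100; n_noise <- 400
  hits <- stats::pnorm(1) * (n_sig + 1) - 0.5
  fas <- stats::pnorm(-1) * (n_noise + 1) - 0.5
  zh <- stats::qnorm((hits + 0.5) / (n_sig + 1))
  zf <- stats::qnorm((fas + 0.5) / (n_noise + 1))
  expect_equal(zh - zf, 2, tolerance = 1e-12)
  expect_equal(exp((zf^2 - zh^2) / 2), 1, tolerance = 1e-12)
  # d' increases in hit count at fixed false alarms
  mk <- function(h) {
    mm <- matrix(2, 5, 5); diag(mm) <- h; mm
  }
  d_lo <- sdt_measures(mk(10))$dprime[1]
  d_hi <- sdt_measures(mk(16))$dprime[1]
  expect_gt(d_hi, d_lo)
  # corrected rates always inside (0, 1), even with empty cells
  z <- sdt_measures(diag(c(20, 20, 20, 20, 20)))
  expect_true(all(z$hit_rate > 0 & z$hit_rate < 1))
  expect_true(all(z$fa_rate > 0 & z$fa_rate < 1))
  expect_true(all(is.finite(z$dprime)))
})

test_that("two-point thresholds come from the fitted 50% crossing", {
  # perfect step between 1.6 and 1.9 mm brackets the threshold
  st <- simulate_2pd(1.75, slope = Inf, seed = 1)
  th <- two_pd_threshold(st$distance_mm, st$two_felt)
  expect_true(th$estimable)
  expect_gt(th$threshold_mm, 1.6)
  expect_lt(th$threshold_mm, 1.9)
  # symmetric responses around 2.0 mm
  d <- rep(c(1.5, 2.5), each = 10)
  r <- rep(c(0, 1, 1, 0), c(8, 2, 8, 2))
  th2 <- two_pd_threshold(d, r)
  expect_equal(th2$threshold_mm, 2.0, tolerance = 1e-6)
  # recovery at large n
  big <- simulate_2pd(2.5, slope = 6, pin_distances_mm = seq(0.7, 4.3, 0.3),
                      n_per_distance = 400, seed = 2)
  th3 <- two_pd_threshold(big$distance_mm, big$two_felt)
  expect_lt(abs(th3$threshold_mm - 2.5), 0.1)
  # all-same responses flagged
  expect_warning(bad <- two_pd_threshold(c(1, 2, 3), c(1, 1, 1)),
                 "not estimable")
  expect_false(bad$estimable)
})

test_that("per-run thresholds average across runs", {
  runs <- lapply(1:2, function(s)
    simulate_2pd(2.0, slope = 5, n_per_distance = 100, seed = s))
  out <- two_pd_threshold_runs(runs)
  expect_equal(out$n_estimable, 2)
  expect_equal(out$threshold_mm, mean(out$per_run))
  expect_lt(abs(out$threshold_mm - 2.0), 0.25)
})

test_that("simulated confusion pipeline recovers the generating neighbour profile", {
  # confusion model with strongly distance-decaying errors
  probs <- 0.25 ^ abs(outer(1:5, 1:5, `-`))
  probs <- probs / rowSums(probs)
  tr <- simulate_mislocalization(probs, n_trials_per_digit = 4000, seed = 9)
  conf <- confusion_from_trials(tr)
  obs <- neighbor_counts(conf)$observed
  # expected proportions from the generating model
  dist <- abs(outer(1:5, 1:5, `-`))
  exp_k <- vapply(1:4, function(k) sum(probs[dist == k]) / 5, numeric(1))
  exp_k <- exp_k * 5 * 4000
  # within Monte-Carlo error (multinomial SD ~ sqrt(expected))
  expect_true(all(abs(obs - exp_k) < 5 * sqrt(exp_k) + 5))
  # observed errors exceed the flat-chance model for near neighbours
  ce <- chance_expected(sum(obs))
  expect_gt(obs[1], ce$expected[1])
  expect_lt(obs[4], ce$expected[4])
})
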