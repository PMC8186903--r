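test_that("phase designs have the protocol's volume count and mirror order", {
  d <- make_phase_design("forward", 20, 5.12, 2)
  expect_identical(d$n_volumes, 256L)
  expect_equal(nrow(d$onsets), 100)  # 20 cycles x 5 fingers

  mini <- make_phase_design("forward", 1, 2, 2)
  expect_identical(mini$n_volumes, 5L)
  expect_equal(position_to_digit(mini$stimulus_position), 1:5)

  rev2 <- make_phase_design("reverse", 5, 5.12, 2)
  expect_equal(rev2$onsets$digit, rep(5:1, 5))
  fw2 <- make_phase_design("forward", 5, 5.12, 2)
  expect_equal(rev2$onsets$digit, rev(fw2$onsets$digit))

  expect_error(make_phase_design("forward", 4, 5.12, 2), "divisible")
})

test_that("block design honours trial structure, pause mix and run rule", {
  for (seed in 1:3) {
    d <- make_block_design(seed = seed)
    expect_identical(d$n_volumes, 208L)  # 50 x 5.12 + 35 x 2 + 15 x 6 = 416 s
    expect_equal(as.vector(table(d$onsets$digit)), rep(10, 5))
    gaps <- diff(d$onsets$onset) - 5.12
    expect_true(all(abs(gaps - 2) < 1e-9 | abs(gaps - 6) < 1e-9))
    expect_true(all(rle(d$onsets$digit)$lengths <= 2))
    # 35 short + 15 long pauses: 50 x 5.12 + 35 x 2 + 15 x 6 = 416 s
    expect_equal(d$n_volumes * d$tr_s, 416)
  }

  d1 <- make_block_design(seed = 7)
  d2 <- make_block_design(seed = 7)
  expect_identical(d1$onsets, d2$onsets)

  tiny <- make_block_design(1, 1.0, 2, 6, 2, 2, seed = 1)
  expect_equal(nrow(tiny$onsets), 5)
  expect_true(all(abs(diff(tiny$onsets$onset) - 4) < 1e-9))
})

test_that("cortex patch is a valid connected mesh with a monotone gradient", {
  p <- make_cortex_patch(c(10, 10), seed = 1)
  expect_equal(nrow(p$vertices), 100)
  expect_equal(nrow(p$faces), 162)
  expect_true(all(p$faces >= 1 & p$faces <= 100))
  # preferred position monotone along rows
  row_of <- rep(1:10, each = 10)
  expect_true(all(diff(tapply(p$preferred_position, row_of, unique)) > 0))
  expect_true(all(p$preferred_position >= -12.5 &
                    p$preferred_position <= 12.5))
  expect_true(all(p$tuning_sigma >= 0.5))
  expect_error(make_cortex_patch(c(4, 4), sigma_range = c(0.1, 1)), "0.5")

  tiny <- make_cortex_patch(c(2, 2), seed = 1)
  expect_equal(nrow(tiny$vertices), 4)
  expect_equal(nrow(tiny$faces), 2)
})

test_that("noiseless BOLD peaks at the tuned epoch and is flat at zero gain", {
  p <- make_cortex_patch(c(5, 2), sigma_range = c(1, 1.5), seed = 1)
  d <- make_phase_design("forward", n_cycles = 5)
  ts <- simulate_bold(p, d, noise_sd = 0, seed = 1)
  # vertex tuned to D3 (position 0): response maximal a few volumes after
  # the D3 epoch within each cycle
  v <- which(abs(p$preferred_position) < 1e-9)[1]
  y <- ts$data[, v]
  cyc_len <- 64 / 5  # not integer; use DFT phase instead of argmax
  fm <- fourier_analyze(ts, 5)
  peak_s <- fm$phase[v] / (2 * pi) * (64 * 2 / 5)
  d3_mid <- 2.5 * 5.12
  expect_lt(abs(peak_s - (d3_mid + hrf_phase_delay(25.6))), 2.6)

  p0 <- make_cortex_patch(c(3, 3), gain = 0, seed = 1)
  ts0 <- simulate_bold(p0, d, noise_sd = 0, seed = 1)
  expect_true(all(abs(ts0$data - 100) < 1e-12))

  # tuned vertex has larger cycle-bin DFT amplitude than a flat-tuning one
  pflat <- make_cortex_patch(c(5, 2), sigma_range = c(24, 25), seed = 1)
  tsf <- simulate_bold(pflat, d, noise_sd = 0, seed = 1)
  a_tuned <- Mod(brute_dft_coef(ts$data[, v], 5))
  a_flat <- Mod(brute_dft_coef(tsf$data[, v], 5))
  expect_gt(a_tuned, a_flat)
})

test_that("bold simulation is reproducible and validates inputs", {
  p <- make_cortex_patch(c(3, 3), seed = 1)
  d <- make_phase_design("forward", n_cycles = 5)
  a <- simulate_bold(p, d, noise_sd = 1, ar1_coef = 0.3, seed = 9)
  b <- simulate_bold(p, d, noise_sd = 1, ar1_coef = 0.3, seed = 9)
  expect_identical(a$data, b$data)
  expect_error(simulate_bold(p, d, noise_sd = -1), "non-negative")
})

test_that("resting simulation matches the target correlation structure", {
  rs <- simulate_resting(corr_matrix = diag(5), n_volumes = 10000, seed = 1)
  cc <- stats::cor(rs$data)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)

  r2 <- matrix(1, 2, 2)
  ts2 <- simulate_resting(2, r2, n_volumes = 100, seed = 1)
  expect_lt(max(abs(ts2$data[, 1] - ts2$data[, 2])), 1e-10)

  a <- simulate_resting(seed = 4); b <- simulate_resting(seed = 4)
  expect_identical(a$data, b$data)

  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(simulate_resting(5, bad), "semi-definite")
})

test_that("mislocalization simulator reproduces its confusion model", {
  tr <- simulate_mislocalization(diag(5), seed = 1)
  expect_equal(nrow(tr), 100)
  expect_true(all(tr$reported_digit == tr$stimulated_digit))

  unif <- matrix(0.2, 5, 5)
  tru <- simulate_mislocalization(unif, n_trials_per_digit = 2000, seed = 2)
  conf <- confusion_from_trials(tru)
  expect_true(all(abs(conf / 2000 - 0.2) < 0.03))

  a <- simulate_mislocalization(unif, seed = 3)
  b <- simulate_mislocalization(unif, seed = 3)
  expect_identical(a$reported_digit, b$reported_digit)

  expect_error(simulate_mislocalization(matrix(0.3, 5, 5)), "sum to 1")
})

test_that("staircase converges to the 79.4% point and is seeded", {
  lad <- monofilament_ladder()
  expect_equal(nrow(lad), 12)
  expect_equal(lad$level, log10(lad$weight_g * 1e4))

  # deterministic step observer: estimate at the step level
  st <- simulate_staircase(lad$level[6], psychometric_slope = Inf, seed = 1)
  expect_true(st$converged)
  expect_lt(abs(st$threshold - lad$level[6]),
            mean(diff(lad$level)) + 1e-9)

  # logistic observer, many runs: mean estimate near the 79.4% level
  thr <- lad$level[5]; slope <- 8
  target <- thr + stats::qlogis(0.5^(1 / 3)) / slope
  ests <- vapply(1:40, function(s)
    simulate_staircase(thr, slope, seed = s)$threshold, numeric(1))
  expect_lt(abs(mean(ests) - target), 0.25)

  a <- simulate_staircase(thr, 8, seed = 11)
  b <- simulate_staircase(thr, 8, seed = 11)
  expect_identical(a$tracks, b$tracks)
})

test_that("two-point simulator is a logistic in distance", {
  # step observer
  st <- simulate_2pd(1.75, slope = Inf, seed = 1)
  expect_true(all(st$two_felt[st$distance_mm >= 1.75] == 1))
  expect_true(all(st$two_felt[st$distance_mm < 1.75] == 0))
  # p(two) at threshold is 0.5
  big <- simulate_2pd(1.6, slope = 5, pin_distances_mm = 1.6,
                      n_per_distance = 4000, seed = 2)
  expect_lt(abs(mean(big$two_felt) - 0.5), 0.03)
  # default design: 8 distances x 10 reps
  expect_equal(nrow(simulate_2pd(2, seed = 1)), 80)
})
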