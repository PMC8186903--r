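# shared small fixtures, built in code

# 64-volume travelling-wave pair (5 cycles, 5.12 s/finger, TR 2 s)
small_phase_pair <- function(patch, seed = 1) {
  fw <- make_phase_design("forward", n_cycles = 5)
  rv <- make_phase_design("reverse", n_cycles = 5)
  list(forward = fw, reverse = rv,
       ts_forward = simulate_bold(patch, fw, noise_sd = 0, seed = seed),
       ts_reverse = simulate_bold(patch, rv, noise_sd = 0,
                                  seed = seed + 1))
}

# unit square mesh: two triangles sharing the 1-4 diagonal
square_mesh <- function(diagonal = TRUE) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  f <- if (diagonal) rbind(c(1, 2, 4), c(1, 4, 3))
  else rbind(c(1, 2, 3), c(2, 4, 3))
  list(vertices = v, faces = f)
}

# brute-force DFT of one series (direct O(n^2) sum), bin k (cycles/run)
brute_dft_coef <- function(x, k) {
  n <- length(x)
  t <- 0:(n - 1)
  sum((x - mean(x)) * exp(-2i * pi * k * t / n))
}
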