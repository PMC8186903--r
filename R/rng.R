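## Seed handling: every generator takes an explicit seed, seeds R's RNG for
## the duration of the call, and restores the caller's RNG state on exit, so
## no global state leaks between calls.
local_rng <- function(seed, envir = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  cleanup <- bquote({
    if (is.null(.(old))) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", .(old), envir = globalenv())
    }
  })
  do.call(on.exit, list(cleanup, TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

## derive a stream of sub-seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), n >= 1)
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483647L
}
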