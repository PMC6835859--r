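# Internal RNG helpers.
#
# All stochastic code in the package draws from explicit seeded streams so
# that stimuli, synthetic datasets and simulations are reproducible
# independently of the caller's RNG state.

# A small self-contained RNG stream: each draw runs under its own
# .Random.seed, saving and restoring the caller's global state.
local_rng <- function(seed) {
  state <- NULL
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, globalenv())
      }
    })
    f()
  }
  list(
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) run(function() stats::rbinom(n, size, prob)),
    sample_int = function(n, size, replace = FALSE) {
      run(function() sample.int(n, size, replace = replace))
    }
  )
}

# Deterministic substream seed derivation (multiplicative-congruential mix,
# kept below 2^31 so the result is a valid R integer seed).
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (id in c(...)) {
    s <- (s * 48271 + (as.numeric(id) %% 65536) * 8191 + 12345) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
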