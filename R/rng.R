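#' Derive a reproducible sub-seed from a master seed and a key path
#'
#' All randomness in the package flows from one integer master seed. Each
#' stochastic component draws its own sub-seed with `af_subseed()` so that
#' cohorts are reproducible piecewise: regenerating subject 17 of a cohort
#' gives bit-identical output whether or not subjects 1..16 were generated.
#'
#' The mixer is a Lehmer-style multiplicative congruential hash over the key
#' path, computed in doubles (all intermediates stay below 2^53, and the
#' result below 2^31, so arithmetic is exact).
#'
#' @param seed integer master seed.
#' @param ... key path: integers and/or short strings (e.g. `"rec"`, 17L).
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' af_subseed(1, "cohort", 5L) == af_subseed(1, "cohort", 5L)
af_subseed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  a <- 48271
  mix <- function(state, k) {
    state <- (state * a) %% m
    ((state + (k * 69621) %% m) * a) %% m
  }
  key_num <- function(k) {
    if (is.character(k)) {
      sum(utf8ToInt(k) * seq_along(utf8ToInt(k)) * 131) %% m
    } else {
      as.numeric(k) %% m
    }
  }
  state <- (as.numeric(seed) %% (m - 1)) + 1
  for (k in list(...)) state <- mix(state, key_num(k))
  state <- mix(state, 1)
  as.integer(state %% (m - 2) + 1)
}

# Evaluate an expression with the global RNG seeded from a sub-seed and
# restored afterwards, so package internals never disturb user RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Uniform in [0,1) from an integer key path, without touching the RNG stream.
# Used for name-keyed weight initialization (see model module).
hash_unit <- function(seed, ...) {
  af_subseed(seed, ...) / 2147483647
}
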