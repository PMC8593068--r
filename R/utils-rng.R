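# RNG plumbing: every stochastic operation takes an explicit integer seed and
# runs in a locally scoped RNG so that no call mutates the caller's random
# state.  Sub-stream seeds are derived from the master seed with a Lehmer-style
# multiplicative hash kept strictly below 2^31 (all arithmetic stays within
# the exact-integer range of doubles).

#' Derive a reproducible sub-stream seed
#'
#' Hashes a master seed together with an arbitrary sequence of small integer
#' labels (trial index, condition index, arm index, round, ...) into a seed in
#' `[0, 2^31 - 2]`. Used so that every (trial, condition, arm) cell of a
#' simulated study has its own reproducible random stream.
#'
#' @param master integer master seed.
#' @param ... integer labels identifying the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 1, 2)
derive_seed <- function(master, ...) {
  m <- 2147483647
  a <- 48271
  h <- abs(as.numeric(master)) %% m
  for (x in c(...)) {
    h <- (h * a) %% m
    h <- (h + abs(as.numeric(x))) %% m
  }
  h <- (h * a) %% m
  as.integer(h)
}

# Evaluate `code` under a temporary RNG seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Clip to [lo, hi]; vectorised.
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
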