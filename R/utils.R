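# Internal RNG plumbing. All user-facing randomness goes through explicit
# seed arguments; the global .Random.seed is always restored afterwards so
# calling package functions never perturbs a user's RNG stream.

get_global_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

set_global_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get_global_rng()
  on.exit(set_global_rng(old), add = TRUE)
  set.seed(seed)
  expr
}

# Evaluate `expr` with .Random.seed = state; return the value and the
# advanced state. Used by the environment process to own a private stream.
with_rng_state <- function(state, expr) {
  old <- get_global_rng()
  on.exit(set_global_rng(old), add = TRUE)
  set_global_rng(state)
  value <- expr
  list(value = value, state = get_global_rng())
}

# Deterministically derive `n` sub-seeds (< 2^31) from a master seed, so a
# sweep can hand independent seeds to networks, defect sets and environments.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
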