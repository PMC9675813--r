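#' Initialize the fluctuating binary environment
#'
#' Draws the initial environmental condition: each of the `H` input bits is
#' set independently to 1 with the input-activity probability `I`. The
#' returned process object carries its own RNG stream, so stepping it never
#' touches (and is never disturbed by) the global RNG.
#'
#' @param H input width (number of pathways).
#' @param I input activity: probability that a redrawn bit is active.
#' @param seed integer RNG seed for the environment stream.
#' @param change_prob per-step probability that a bit is preselected for
#'   change (default 0.2).
#' @return An object of class `environment_process` with fields `H`, `I`,
#'   `change_prob`, `current` (the 0/1 input vector), `seed` and `t`.
#'
#' @examples
#' env <- init_inputs(H = 10, I = 0.6, seed = 1)
#' env <- step_inputs(env)
#' env$current
#' @export
init_inputs <- function(H, I, seed, change_prob = 0.2) {
  H <- check_count(H, "H")
  I <- check_fraction(I, "I")
  change_prob <- check_fraction(change_prob, "change_prob")
  seed <- check_count(seed, "seed", min = 0L)
  st <- with_rng_state(with_seed(seed, get_global_rng()),
                       as.integer(stats::runif(H) < I))
  structure(
    list(H = H, I = I, change_prob = change_prob, current = st$value,
         seed = seed, t = 0L, rng_state = st$state),
    class = "environment_process")
}

#' Advance the environment by one time step
#'
#' Each input bit is independently preselected for change with probability
#' `change_prob`; every preselected bit is then redrawn, set to 1 with
#' probability `I` and to 0 otherwise. Non-preselected bits keep their value.
#' Each bit is therefore a two-state Markov chain with flip probabilities
#' `P(0 -> 1) = change_prob * I` and `P(1 -> 0) = change_prob * (1 - I)`, so
#' the stationary activity level is exactly `I`.
#'
#' @param env an [environment_process][init_inputs].
#' @return The advanced `environment_process` (with `t` incremented).
#' @export
step_inputs <- function(env) {
  stopifnot(inherits(env, "environment_process"))
  st <- with_rng_state(env$rng_state, {
    sel <- stats::runif(env$H) < env$change_prob
    cur <- env$current
    if (any(sel)) cur[sel] <- as.integer(stats::runif(sum(sel)) < env$I)
    cur
  })
  env$current <- st$value
  env$rng_state <- st$state
  env$t <- env$t + 1L
  env
}

# Generate the inputs for steps 1..n as an n x H matrix: row 1 is the
# current vector, each later row one fluctuation step further.
env_input_matrix <- function(env, n) {
  out <- matrix(0L, n, env$H)
  out[1L, ] <- env$current
  if (n >= 2L) {
    for (t in 2L:n) {
      env <- step_inputs(env)
      out[t, ] <- env$current
    }
  }
  list(inputs = out, env = env)
}

#' @export
print.environment_process <- function(x, ...) {
  cat(sprintf(
    "<environment_process> H=%d, I=%.3g, change_prob=%.3g, t=%d, seed=%d\n",
    x$H, x$I, x$change_prob, x$t, x$seed))
  cat("  current: ", paste(x$current, collapse = ""), "\n", sep = "")
  invisible(x)
}
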