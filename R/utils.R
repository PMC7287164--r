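# Seed handling: every stochastic entry point routes through these helpers so
# results are reproducible from a single integer and the caller's RNG state is
# never disturbed.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards.
#'
#' @param seed Integer seed, or NULL to use (and advance) the current RNG.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream of child seeds from a master seed
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Indices of samples inside a half-open window
#'
#' Windows are interpreted as half-open `[start, end)`: a sample at time `t`
#' belongs to the window iff `start <= t < end`. This avoids double-counting
#' boundary samples across adjacent windows.
#'
#' @param times_s Numeric vector of sample times.
#' @param window_s Two-element numeric `(start, end)` in seconds.
#' @return Integer indices into `times_s`.
#' @keywords internal
window_index <- function(times_s, window_s) {
  stopifnot(length(window_s) == 2, window_s[1] < window_s[2])
  which(times_s >= window_s[1] & times_s < window_s[2])
}
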