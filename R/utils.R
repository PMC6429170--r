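# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `expr`, and restores the previous RNG state so
#' that seeded package internals never disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a sub-stream seed from a master seed
#'
#' Deterministic expansion of one master seed into per-stage / per-user
#' streams. Kept strictly below 2^31 so the result is a valid R integer.
#'
#' @param seed Master integer seed.
#' @param stream Non-negative integer stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(seed)) %% m)
  # two rounds of a multiplicative congruential mix (Lehmer-style)
  s <- (s * 48271) %% m
  s <- (s + as.numeric(stream) * 16807 + 1) %% m
  as.integer(s)
}

# Shannon entropy in bits of a probability vector (zero-safe).
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# stop() with a class so tests can assert on error types
err <- function(msg, class) {
  stop(structure(class = c(class, "erpleak_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
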