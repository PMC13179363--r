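# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed, staying within 32-bit range
#' @noRd
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1103L + 7919 * as.numeric(k)) %% 2147483629
}

#' Wrap phase angles to (-pi, pi]
#' @noRd
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # %% maps pi -> -pi; restore the (-pi, pi] convention
  out[out == -pi] <- pi
  out
}

#' Integer-sample delay, zero-padded at the start
#' @noRd
delay_samples <- function(x, d) {
  n <- length(x)
  if (d == 0) return(x)
  stopifnot(d > 0, d < n)
  c(numeric(d), x[seq_len(n - d)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
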