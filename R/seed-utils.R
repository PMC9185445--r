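# RNG plumbing. All stochastic operations take an explicit integer seed and
# leave the caller's RNG state untouched.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded operations never perturb an enclosing
#' simulation.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a master seed
#'
#' Deterministically fans a master seed out into per-stage / per-item seeds
#' using a multiplicative congruential mix. The result is always a positive
#' integer below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param ... One or more integer stream identifiers (stage index, patient
#'   index, ...).
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  ks <- c(...)
  m <- 2147483647
  s <- as.double(seed) %% m
  for (k in ks) {
    s <- (s * 48271 + (as.double(k) + 1) * 9973 + 12345) %% m
  }
  as.integer(if (s == 0) 1 else s)
}
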