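#' Evaluate an expression under a local, seeded RNG
#'
#' All randomness in the package flows through this helper: a single integer
#' seed deterministically drives the draws, and the caller's global RNG state
#' (`.Random.seed`) is restored afterwards, so no package function perturbs
#' the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

# A mutable RNG scope: opens a seeded stream that stays live across several
# draws inside one function (training loops interleave index sampling, noise
# and dropout masks, and the draw ORDER is part of the determinism contract).
rng_scope_open <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  old
}

rng_scope_close <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a stream-specific child seed from a base seed; double arithmetic
# (exact below 2^53) avoids integer overflow, and the modulus keeps every
# derived seed a valid 32-bit integer even when derivations are chained.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483587)
}
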