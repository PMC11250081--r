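# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG state, restoring the caller's state
#'
#' All stochastic operations in the package route their `seed` argument
#' through this helper so that results are pure functions of
#' (parameters, seed) and never disturb the user's RNG stream.
#'
#' @param seed integer scalar, or NULL to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
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
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

# Derive a reproducible child seed from a parent seed and one or more
# integer indices.  Keeps results below 2^31 so set.seed() accepts them.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

abort_dscreen <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "dscreen_error"), ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
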