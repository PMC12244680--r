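#' Evaluate an expression with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random number
#' generator state afterwards, so library functions never disturb ambient
#' randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a base seed and index terms
#'
#' Deterministic integer mixing so that every replicate / sweep cell gets its
#' own reproducible stream. Result is always in [1, 2^31 - 2].
#'
#' @param seed Base integer seed.
#' @param ... Further non-negative integer terms (cell index, replicate, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629 # large prime < 2^31
  x <- as.numeric(seed) %% m
  for (term in list(...)) {
    x <- (x * 48271 + as.numeric(term) + 1) %% m
  }
  as.integer(x + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_af <- function(fmt, ..., class = "aridfarm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
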