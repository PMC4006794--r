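#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so seeded operations do not disturb the caller's
#' random stream. With `seed = NULL` the expression runs on the ambient
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
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
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# harmonic numbers used throughout the diversity and coalescent code:
# a_n = sum_{i=1}^{n-1} 1/i, b_n = sum_{i=1}^{n-1} 1/i^2
harmonic_a <- function(n) {
  if (n < 2) return(0)
  sum(1 / seq_len(n - 1L))
}

harmonic_b <- function(n) {
  if (n < 2) return(0)
  sum(1 / seq_len(n - 1L)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
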