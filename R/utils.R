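#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores whatever RNG
#' state the session had before. All stochastic operations in the package
#' route their seeds through this helper so that results are reproducible
#' without clobbering the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a base seed
#'
#' Deterministic mixing keeping the result in the 32-bit integer range, so
#' that pipeline stages each get an independent but reproducible stream.
#'
#' @param seed base integer seed.
#' @param i stage index (any non-negative integer).
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 11 * as.double(i) + 7) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_pg <- function(...) stop(sprintf(...), call. = FALSE)

# Validate a +1/-1 matrix (segments x features)
check_pm1_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_pg("%s must be a numeric matrix", what)
  }
  if (!all(m == 1 | m == -1)) {
    stop_pg("%s must contain only +1/-1 values", what)
  }
  invisible(m)
}
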