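#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then restores
#' the caller's RNG state, so that seeded simulations do not perturb an
#' enclosing random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

#' @keywords internal
is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(abs(x - round(x)) < 1e-8)
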