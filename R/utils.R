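#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so library calls never clobber a user's stream.  A
#' `NULL` seed leaves the current stream untouched.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# scalar checks used by config validators
.check_prop <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  x
}

.check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("`%s` must be a single finite number >= 0", name), call. = FALSE)
  x
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
      x != round(x))
    stop(sprintf("`%s` must be a single non-negative integer", name), call. = FALSE)
  as.integer(x)
}
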