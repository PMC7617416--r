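#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators are pure functions of (config, seed).
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
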