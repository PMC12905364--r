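#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their `seed` argument and never disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear-interpolation quantile summary of a numeric vector
#' @keywords internal
length_summary <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 0.95, 1), names = FALSE, type = 7)
  data.frame(n = length(x), min = q[1], q1 = q[2], median = q[3],
             q3 = q[4], p95 = q[5], max = q[6])
}

#' Derive a stream-specific 32-bit seed from a master seed
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
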