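# Internal helpers shared across modules.

#' Derive a child seed from a top-level seed
#'
#' All stochastic stages (dropout, per-well trace noise) draw their seeds
#' from one top-level seed through this splitting rule, so a stage rerun in
#' isolation reproduces exactly what it produced inside the full pipeline.
#' The rule is a multiplicative hash over the (seed, stream, index) triple,
#' reduced modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed Integer top-level seed.
#' @param stream Character stream label (e.g. `"dropout"`, `"trace"`).
#' @param index Non-negative integer, e.g. a position index within a stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = "default", index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- (abs(as.numeric(seed)) %% m)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h * 48271 + as.numeric(index) + 1) %% m
  as.integer(h %% (m - 2) + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Stop with a consistent message when a scalar argument is out of range.
check_unit_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
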