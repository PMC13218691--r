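#' @keywords internal
"_PACKAGE"

## Run an expression under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Derive a child seed (kept below 2^31) from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
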