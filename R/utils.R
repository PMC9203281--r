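#' @include AllClasses.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## row variance of a dense matrix without forming large intermediates
.rowVars <- function(x) matrixStats::rowVars(as.matrix(x))
.colVars <- function(x) matrixStats::colVars(as.matrix(x))

.stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)

## derive a stream-specific 32-bit seed from a master seed, so independent
## stages driven by one --seed do not reuse the identical stream
.deriveSeed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

## run an expression under a local RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
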