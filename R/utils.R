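#' @import methods
#' @importFrom stats prcomp rnorm runif sd quantile setNames dist
#' @importFrom utils head tail read.csv write.csv modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib msifusion, .registration = TRUE
NULL

## Evaluate `code` under a temporary RNG state so that package functions are
## deterministic given `seed` without clobbering the caller's stream.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a base seed and a stream label, staying < 2^31.
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

stopIfNot <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
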