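#' @useDynLib pedalbci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a deterministic sub-seed (kept below 2^31) from a base seed and up
# to two stream indices, so nested generators stay independent per seed.
seed_stream <- function(seed, a, b = 0L) {
  s <- (abs(as.numeric(seed)) %% 2147483629) * 48271 +
    as.numeric(a) * 131071 + as.numeric(b) * 8191
  as.integer(s %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
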