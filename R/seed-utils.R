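#' @keywords internal
"_PACKAGE"

## Deterministic substream seeds: every generator draws from its own named
## substream derived from the root seed, so adding one generator never
## perturbs another's output for the same root seed.

# polynomial string hash folded into [0, 2^31 - 2]
.hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h
}

#' Derive a substream seed from a root seed and a stream name
#'
#' @param seed Root integer seed.
#' @param stream Character stream name (e.g. `"proteins"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  (as.integer(seed) %% 2147483647L + .hash_string(stream)) %% 2147483647L
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
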