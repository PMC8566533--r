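## Seed plumbing: all randomness flows from one root seed via named
## sub-streams so that stages (cohort / split / subsets / lesions) can be
## regenerated independently and deterministically.

#' Derive a reproducible sub-stream seed
#'
#' Maps (root seed, stream name, index) to a 31-bit seed by iterated
#' integer hashing, so different stages of the pipeline consume
#' independent, reproducible streams.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @param index optional integer index within the stream.
#' @return An integer in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, stream, index = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% 2147483647
  h <- (h * 69069 + 7 * as.numeric(index) + 1) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

## evaluate expr under a local RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
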