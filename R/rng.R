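#' Derive a deterministic substream seed
#'
#' Maps a master seed plus an arbitrary sequence of labels (epoch, node,
#' branch, stage, ...) to an integer seed by a polynomial rolling hash modulo
#' the Mersenne prime 2^31 - 1.  Every stochastic stage of an optimization run
#' draws its randomness from a substream derived this way, so results are
#' independent of execution order and of the worker count.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the substream.
#' @return A positive integer seed, strictly below 2^31.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- abs(as.numeric(master)) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h) + 1L
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.  Keeps package-internal randomness from
# perturbing (or being perturbed by) user code.
with_substream <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
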