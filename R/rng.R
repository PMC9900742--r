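#' Reproducible random-number streams
#'
#' Every stochastic operation in propsi draws from an explicit stream rather
#' than the global RNG, so that a session, an observer, and an analysis can
#' each be replayed independently. A stream is a mutable handle around a
#' Mersenne-Twister state seeded once; drawing from one stream never disturbs
#' another stream or the user's `.Random.seed`.
#'
#' @param seed Integer seed.
#' @return An object of class `rng_stream`.
#' @export
#' @examples
#' s <- rng_stream(1)
#' with_stream(s, runif(2))
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(abs(seed) %% .Machine$integer.max)
  env$state <- NULL
  class(env) <- "rng_stream"
  env
}

#' Evaluate code under a stream's RNG state
#'
#' @param stream An [rng_stream()].
#' @param code Expression to evaluate; any RNG draws inside it advance the
#'   stream and leave the global RNG untouched.
#' @return The value of `code`.
#' @export
with_stream <- function(stream, code) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  code
}

# Deterministic sub-seed derivation; keeps results < 2^31 so they remain
# valid R integer seeds. Arithmetic stays within double precision.
derive_seed <- function(seed, salt) {
  as.integer(((abs(seed) %% 1e6) * 2017 + abs(salt) * 7919 + 1) %% 2147483647)
}
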