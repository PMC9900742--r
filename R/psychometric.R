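#' Psychometric function parameters
#'
#' The task models the probability of judging the left (test) foot as more
#' forward at a foot-position difference `s` (left minus right ankle-marker
#' position, mm; positive = left foot forward) as a cumulative Gaussian with
#' mean `alpha` and standard deviation `beta`. `alpha` is the point of
#' subjective equality (PSE): the foot-position difference at which "left"
#' and "right" judgements are equally likely. `beta` is the uncertainty:
#' the SD of the cdf, inversely related to its slope, reflecting sensory
#' noise. Both are in millimetres.
#'
#' @param alpha PSE in mm; must be finite.
#' @param beta Uncertainty (SD) in mm; must be strictly positive.
#' @return A `psychometric_params` object (named list with `alpha`, `beta`).
#' @export
#' @examples
#' psychometric_params(12, 18)
psychometric_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("`beta` (uncertainty, mm) must be a single finite value > 0", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "psychometric_params")
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf("Psychometric parameters: PSE (alpha) = %.2f mm, uncertainty (beta) = %.2f mm\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Probability of a "left" judgement at a stimulus position
#'
#' Evaluates the cumulative-Gaussian psychometric function: the probability
#' that the observer reports the left (test) foot as more forward when it is
#' placed at foot-position difference `stimulus`.
#'
#' @param params A [psychometric_params()] object (or anything coercible via
#'   `alpha`/`beta` elements).
#' @param stimulus Stimulus position(s), mm. Vectorised.
#' @return Probabilities in `[0, 1]`, same length as `stimulus`.
#' @export
#' @examples
#' psychometric_prob(psychometric_params(0, 20), c(-20, 0, 20))
psychometric_prob <- function(params, stimulus) {
  params <- as_psychometric_params(params)
  stopifnot(is.numeric(stimulus), all(is.finite(stimulus)))
  stats::pnorm(stimulus, mean = params$alpha, sd = params$beta)
}

as_psychometric_params <- function(x) {
  if (inherits(x, "psychometric_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    if (all(c("alpha", "beta") %in% names(x))) {
      return(psychometric_params(x$alpha, x$beta))
    }
  }
  stop("cannot interpret `params` as psychometric parameters", call. = FALSE)
}

#' Response labels
#'
#' The two possible answers to "Do you feel your right or left foot is more
#' forward?". `"left"` means the test (left) foot was judged more forward.
#' @name response_labels
#' @export
response_levels <- function() c("left", "right")

#' Simulated observer
#'
#' An observer answers the 2AFC prompt stochastically according to its true
#' psychometric function. Lapse and guess rates default to 0, matching the
#' two-parameter model used for the human assessment; non-zero rates clamp
#' the response probability to `[guess, 1 - lapse]` and are provided for
#' robustness studies only.
#'
#' @param alpha,beta True PSE and uncertainty in mm.
#' @param lapse,guess Lapse/guess probabilities in `[0, 0.5)`; default 0.
#' @param seed Integer seed for the observer's private response stream.
#' @return An `observer` object.
#' @export
#' @examples
#' obs <- observer(12, 18, seed = 1)
#' simulate_response(obs, 0)
observer <- function(alpha, beta, lapse = 0, guess = 0, seed = 1L) {
  params <- psychometric_params(alpha, beta)
  stopifnot(is.numeric(lapse), length(lapse) == 1L, lapse >= 0, lapse < 0.5,
            is.numeric(guess), length(guess) == 1L, guess >= 0, guess < 0.5)
  structure(
    list(params = params, lapse = as.numeric(lapse), guess = as.numeric(guess),
         seed = as.integer(seed), stream = rng_stream(seed)),
    class = "observer"
  )
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf("Simulated observer: alpha = %.2f mm, beta = %.2f mm, lapse = %g, guess = %g\n",
              x$params$alpha, x$params$beta, x$lapse, x$guess))
  invisible(x)
}

#' Draw one 2AFC response from a simulated observer
#'
#' A Bernoulli draw with success probability
#' `guess + (1 - guess - lapse) * psychometric_prob(params, stimulus)`,
#' i.e. the psychometric probability clamped to `[guess, 1 - lapse]`.
#' Responses come from the observer's private stream, so an identical seed
#' and stimulus sequence reproduces the identical response sequence.
#'
#' @param obs An [observer()].
#' @param stimulus Stimulus position, mm (scalar).
#' @return `"left"` or `"right"`.
#' @export
simulate_response <- function(obs, stimulus) {
  stopifnot(inherits(obs, "observer"), is.numeric(stimulus), length(stimulus) == 1L)
  p_left <- obs$guess + (1 - obs$guess - obs$lapse) *
    psychometric_prob(obs$params, stimulus)
  u <- with_stream(obs$stream, stats::runif(1))
  if (u < p_left) "left" else "right"
}
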