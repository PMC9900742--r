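#' Parameter grid for the Psi algorithm
#'
#' The Psi algorithm maintains a joint posterior over a discrete grid of
#' (alpha, beta) pairs. The default grid spans the full stimulus range for
#' the PSE (so no attainable threshold falls off the grid) and generously
#' exceeds observed human uncertainty values (around 18 mm) for beta.
#'
#' @param alpha Strictly increasing vector of candidate PSE values, mm.
#' @param beta Strictly increasing vector of candidate uncertainty values,
#'   mm; all > 0.
#' @return A `psi_grid` object.
#' @export
#' @examples
#' g <- psi_grid(alpha = seq(-100, 100, 5), beta = seq(2, 40, 2))
psi_grid <- function(alpha = seq(-100, 100, by = 1),
                     beta = seq(1, 60, by = 0.5)) {
  stopifnot(is.numeric(alpha), length(alpha) >= 1, all(is.finite(alpha)),
            is.numeric(beta), length(beta) >= 1, all(is.finite(beta)))
  if (length(alpha) > 1 && any(diff(alpha) <= 0)) {
    stop("`alpha` grid must be strictly increasing", call. = FALSE)
  }
  if (length(beta) > 1 && any(diff(beta) <= 0)) {
    stop("`beta` grid must be strictly increasing", call. = FALSE)
  }
  if (any(beta <= 0)) stop("`beta` grid values must be > 0", call. = FALSE)
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         # cells in column-major (alpha fastest) order
         alpha_cell = rep(as.numeric(alpha), times = length(beta)),
         beta_cell = rep(as.numeric(beta), each = length(alpha))),
    class = "psi_grid"
  )
}

#' @export
print.psi_grid <- function(x, ...) {
  cat(sprintf("Psi parameter grid: %d alpha x %d beta = %d cells\n",
              length(x$alpha), length(x$beta),
              length(x$alpha) * length(x$beta)))
  invisible(x)
}

#' Candidate stimulus positions
#'
#' The treadmill can place the test foot at 21 foot-position differences:
#' every 10 mm from -100 to +100 mm.
#'
#' @param positions Ordered numeric vector of stimulus positions, mm.
#' @return A numeric vector of class `stimulus_set`.
#' @export
stimulus_set <- function(positions = seq(-100, 100, by = 10)) {
  stopifnot(is.numeric(positions), length(positions) >= 2,
            all(is.finite(positions)), all(diff(positions) > 0))
  structure(as.numeric(positions), class = "stimulus_set")
}

#' Independent product prior over the parameter grid
#'
#' Maximum-entropy-style prior: alpha ~ Normal(0, 20 mm) (no prior bias,
#' wide), beta ~ Exponential(mean 20 mm), evaluated at the grid points and
#' normalized to total mass 1. Because the prior is discretized and beta is
#' truncated to the grid's extent, the discrete marginal beta mean differs
#' slightly from 20 mm (quadrature gap shrinks with grid refinement).
#'
#' @param grid A [psi_grid()].
#' @param alpha_mean,alpha_sd Mean and SD of the Gaussian alpha prior, mm.
#' @param beta_mean Mean of the exponential beta prior, mm.
#' @return Normalized mass vector over grid cells (alpha varying fastest).
#' @export
psi_prior <- function(grid, alpha_mean = 0, alpha_sd = 20, beta_mean = 20) {
  stopifnot(inherits(grid, "psi_grid"))
  if (length(grid$alpha_cell) == 0) stop("empty parameter grid", call. = FALSE)
  w <- stats::dnorm(grid$alpha_cell, alpha_mean, alpha_sd) *
    stats::dexp(grid$beta_cell, rate = 1 / beta_mean)
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    stop("prior mass vanishes on this grid; widen the grid", call. = FALSE)
  }
  w / total
}

#' Likelihood lookup tables
#'
#' Precomputes `p(left | alpha, beta, s)` for every grid cell and candidate
#' stimulus; the "right" table is its complement and is derived on the fly.
#'
#' @param grid A [psi_grid()].
#' @param stimuli A [stimulus_set()] (or numeric vector of positions).
#' @return Matrix with one row per grid cell, one column per stimulus.
#' @export
build_lookup_tables <- function(grid, stimuli = stimulus_set()) {
  stopifnot(inherits(grid, "psi_grid"), is.numeric(stimuli))
  vapply(
    as.numeric(stimuli),
    function(s) stats::pnorm(s, grid$alpha_cell, grid$beta_cell),
    numeric(length(grid$alpha_cell))
  )
}

#' Initialise a Psi procedure
#'
#' Bundles the grid, stimulus set, likelihood tables, and prior mass into a
#' `psi` state object. The state is immutable: [psi_update()] returns a new
#' state and never modifies its input.
#'
#' @inheritParams build_lookup_tables
#' @inheritParams psi_prior
#' @return A `psi` state object.
#' @export
#' @examples
#' st <- psi_new(psi_grid(seq(-40, 40, 10), seq(5, 30, 5)))
#' select_next_stimulus(st)
psi_new <- function(grid = psi_grid(), stimuli = stimulus_set(),
                    alpha_mean = 0, alpha_sd = 20, beta_mean = 20) {
  stimuli <- if (inherits(stimuli, "stimulus_set")) stimuli else stimulus_set(stimuli)
  structure(
    list(grid = grid,
         stimuli = as.numeric(stimuli),
         p_left = build_lookup_tables(grid, stimuli),
         mass = psi_prior(grid, alpha_mean, alpha_sd, beta_mean),
         trial_count = 0L,
         stimulus_history = numeric(0),
         response_history = character(0)),
    class = "psi"
  )
}

#' @export
print.psi <- function(x, ...) {
  est <- psi_estimate(x)
  cat(sprintf(
    "Psi state: %d trials; alpha-hat = %.2f mm, beta-hat = %.2f mm; posterior entropy = %.2f bits\n",
    x$trial_count, est$alpha, est$beta, posterior_entropy(x)))
  invisible(x)
}

stimulus_index <- function(state, stimulus) {
  idx <- which(abs(state$stimuli - stimulus) < 1e-9)
  if (length(idx) != 1L) {
    stop(sprintf("stimulus %g mm is not in the stimulus set", stimulus),
         call. = FALSE)
  }
  idx
}

#' Bayesian posterior update after one trial
#'
#' Multiplies the current joint mass by the likelihood of the observed
#' response at the delivered stimulus and renormalizes (the denominator is
#' the marginal likelihood of the response). The posterior of trial t is the
#' prior of trial t+1.
#'
#' @param state A `psi` state.
#' @param stimulus Delivered stimulus, mm; must belong to the stimulus set.
#' @param response `"left"` or `"right"`.
#' @return A new `psi` state; the input is unchanged.
#' @export
psi_update <- function(state, stimulus, response) {
  stopifnot(inherits(state, "psi"))
  response <- match.arg(response, response_levels())
  idx <- stimulus_index(state, stimulus)
  like <- if (response == "left") state$p_left[, idx] else 1 - state$p_left[, idx]
  w <- state$mass * like
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    stop(sprintf(
      "degenerate update: response '%s' at %g mm has zero marginal likelihood on this grid",
      response, stimulus), call. = FALSE)
  }
  state$mass <- w / total
  state$trial_count <- state$trial_count + 1L
  state$stimulus_history <- c(state$stimulus_history, stimulus)
  state$response_history <- c(state$response_history, response)
  state
}

#' Shannon entropy of the current joint posterior, in bits
#'
#' @param state A `psi` state (or a bare mass vector).
#' @return Entropy in bits; `0 * log 0` is taken as 0.
#' @export
posterior_entropy <- function(state) {
  mass <- if (inherits(state, "psi")) state$mass else state
  entropy_bits_kernel(as.numeric(mass))
}

#' Expected one-step-ahead posterior entropy per candidate stimulus
#'
#' For each candidate stimulus s, computes
#' `H(s, left) p(left | s) + H(s, right) p(right | s)`, where `H(s, r)` is
#' the Shannon entropy (bits) of the posterior that would result from
#' response r at s, and `p(r | s)` is the posterior-predictive response
#' probability.
#'
#' @param state A `psi` state.
#' @param stimulus Optional subset of stimuli to evaluate (default: all).
#' @return Named numeric vector of expected entropies (bits).
#' @export
expected_entropy <- function(state, stimulus = NULL) {
  stopifnot(inherits(state, "psi"))
  if (is.null(stimulus)) {
    cols <- seq_along(state$stimuli)
  } else {
    cols <- vapply(stimulus, function(s) stimulus_index(state, s), integer(1))
  }
  eh <- expected_entropy_kernel(state$mass, state$p_left[, cols, drop = FALSE])
  stats::setNames(eh, state$stimuli[cols])
}

#' Entropy-minimizing stimulus selection
#'
#' Returns the candidate stimulus with the smallest expected one-step-ahead
#' posterior entropy. Ties (within 1e-12 relative tolerance, e.g. the exact
#' mirror pairs produced by a symmetric prior) are broken deterministically:
#' smallest absolute position first, then the negative (left-behind)
#' candidate.
#'
#' @param state A `psi` state.
#' @return A single stimulus position, mm.
#' @export
select_next_stimulus <- function(state) {
  eh <- expected_entropy(state)
  m <- min(eh)
  tol <- 1e-12 * max(1, abs(m))
  cand <- state$stimuli[eh <= m + tol]
  cand[order(abs(cand), cand)][1L]
}

#' Marginal posterior over one parameter
#'
#' @param state A `psi` state.
#' @param param `"alpha"` or `"beta"`.
#' @return A tibble with columns `value` (mm) and `mass`.
#' @export
psi_marginal <- function(state, param = c("alpha", "beta")) {
  stopifnot(inherits(state, "psi"))
  param <- match.arg(param)
  na <- length(state$grid$alpha)
  nb <- length(state$grid$beta)
  m <- matrix(state$mass, nrow = na, ncol = nb)
  if (param == "alpha") {
    tibble::tibble(value = state$grid$alpha, mass = rowSums(m))
  } else {
    tibble::tibble(value = state$grid$beta, mass = colSums(m))
  }
}

#' Current parameter estimates (marginal posterior means)
#'
#' @param state A `psi` state.
#' @return A [psychometric_params()] with the marginal means of alpha and
#'   beta.
#' @export
psi_estimate <- function(state) {
  stopifnot(inherits(state, "psi"))
  psychometric_params(sum(state$mass * state$grid$alpha_cell),
                      sum(state$mass * state$grid$beta_cell))
}
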