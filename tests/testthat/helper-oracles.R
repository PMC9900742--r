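# Brute-force reference implementations, written from the definitions and
# kept independent of the package's computational paths.

# product-and-normalize Bayes update over a mass vector
oracle_update <- function(mass, likelihood) {
  w <- mass * likelihood
  w / sum(w)
}

# Shannon entropy in bits, 0 log 0 = 0
oracle_entropy <- function(mass) {
  nz <- mass[mass > 0]
  -sum(nz * log2(nz))
}

# expected one-step-ahead entropy at one stimulus column, by full
# enumeration over the two responses
oracle_expected_entropy <- function(mass, p_left_col) {
  out <- 0
  for (resp in c("left", "right")) {
    like <- if (resp == "left") p_left_col else 1 - p_left_col
    p_resp <- sum(mass * like)
    if (p_resp > 0) {
      out <- out + p_resp * oracle_entropy(oracle_update(mass, like))
    }
  }
  out
}

# exhaustive argmin stimulus selection with the package's documented
# tie-break (smallest |s|, then the negative candidate)
oracle_select <- function(state) {
  eh <- vapply(seq_along(state$stimuli), function(k) {
    oracle_expected_entropy(state$mass, state$p_left[, k])
  }, numeric(1))
  m <- min(eh)
  cand <- state$stimuli[eh <= m + 1e-12 * max(1, abs(m))]
  cand[order(abs(cand), cand)][1]
}

# exhaustive narrowest-window HDI: check every candidate window directly
oracle_hdi <- function(samples, prob = 0.95) {
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(prob * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    lo <- x[i]
    hi <- x[i + m - 1]
    if ((hi - lo) < (best[2] - best[1])) best <- c(lo, hi)
  }
  best
}

# a psi state on a small grid with a randomized (normalized) posterior
random_small_state <- function(seed, n_alpha = 5, n_beta = 5) {
  set.seed(seed)
  grid <- psi_grid(alpha = sort(runif(n_alpha, -80, 80)),
                   beta = sort(runif(n_beta, 2, 40)))
  state <- psi_new(grid, stimulus_set())
  mass <- runif(n_alpha * n_beta)
  state$mass <- mass / sum(mass)
  state
}

# small deterministic estimates table with a known structure
fixture_estimates <- function(n = 6, bias = 0, noise = 0, seed = 1) {
  set.seed(seed)
  t1 <- seq(-10, 30, length.out = n)
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    pse_test1_mm = t1,
    pse_test2_mm = t1 - bias + rnorm(n, 0, noise),
    unc_test1_mm = seq(12, 25, length.out = n),
    unc_test2_mm = seq(12, 25, length.out = n) + rnorm(n, 0, noise)
  )
}

# small session configuration used where full-size sessions are not needed
fast_config <- function(n_trials = 20, seed = 1) {
  session_config(
    n_trials = n_trials,
    grid = psi_grid(alpha = seq(-60, 60, 5), beta = seq(4, 34, 3)),
    preselect_warmup = min(5L, n_trials - 1L),
    seed = seed
  )
}

# study-scale grid used by the simulation studies (2 mm alpha step, 1 mm
# beta step): close to the fine default in accuracy, several times faster
study_grid <- function() psi_grid(alpha = seq(-100, 100, 2), beta = seq(1, 60, 1))
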