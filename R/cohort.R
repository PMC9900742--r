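#' Synthetic cohort specification
#'
#' Describes a population of simulated participants for a two-test
#' (test-retest) study. True PSEs are drawn from Normal(`pse_mean`,
#' `pse_sd`) and true uncertainties from Normal(`unc_mean`, `unc_sd`)
#' truncated to be positive. Population means default to the values typical
#' of healthy adults on this assessment (PSE about 12 mm — people tend to
#' feel their feet aligned when the left foot is actually forward — and
#' uncertainty about 18 mm); the population SDs are wider than the observed
#' cohort so simulated studies span the plausible range. Each test's true
#' parameters can be jittered (`between_test_sd`) and biased
#' (`injected_mean_bias`, `injected_slope_bias`) to create cohorts with
#' known agreement failures: Test 2's true value is
#' `test1 - injected_mean_bias - injected_slope_bias * test1` (so the
#' Test1 - Test2 difference is approximately
#' `injected_mean_bias + injected_slope_bias * true score`).
#'
#' @param n_participants Number of participants (>= 3); default 13.
#' @param pse_mean,pse_sd Population mean/SD of the true PSE, mm.
#' @param unc_mean,unc_sd Population mean/SD of the true uncertainty, mm.
#' @param between_test_sd SD of the per-test jitter on true parameters, mm.
#' @param injected_mean_bias Constant Test1 - Test2 bias, mm.
#' @param injected_slope_bias Proportional bias of the difference on the
#'   true score.
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_participants = 13L,
                        pse_mean = 12, pse_sd = 15,
                        unc_mean = 18.2, unc_sd = 5,
                        between_test_sd = 0,
                        injected_mean_bias = 0,
                        injected_slope_bias = 0,
                        seed = 1L) {
  stopifnot(n_participants >= 3, pse_sd >= 0, unc_sd >= 0, between_test_sd >= 0,
            unc_mean > 0)
  structure(
    list(n_participants = as.integer(n_participants),
         pse_mean = pse_mean, pse_sd = pse_sd,
         unc_mean = unc_mean, unc_sd = unc_sd,
         between_test_sd = between_test_sd,
         injected_mean_bias = injected_mean_bias,
         injected_slope_bias = injected_slope_bias,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

rtrunc_pos <- function(n, mean, sd, stream, lower = 1) {
  # positive-truncated normal by rejection; uncertainty truths must be > 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- with_stream(stream, stats::rnorm(1, mean, sd))
      if (x > lower) break
    }
    out[i] <- x
  }
  out
}

cohort_truths <- function(spec) {
  stream <- rng_stream(spec$seed)
  alpha <- with_stream(stream, stats::rnorm(spec$n_participants, spec$pse_mean, spec$pse_sd))
  beta <- rtrunc_pos(spec$n_participants, spec$unc_mean, spec$unc_sd, stream)
  per_test <- function(truth, test, bias = 0, slope = 0) {
    jit <- with_stream(stream, stats::rnorm(length(truth), 0, spec$between_test_sd))
    t1 <- truth + jit
    if (test == 1) t1 else t1 - bias - slope * truth
  }
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(spec$n_participants)),
    alpha_true = alpha, beta_true = beta,
    alpha_test1 = per_test(alpha, 1),
    alpha_test2 = per_test(alpha, 2, spec$injected_mean_bias, spec$injected_slope_bias),
    beta_test1 = pmax(1, per_test(beta, 1)),
    beta_test2 = pmax(1, per_test(beta, 2))
  )
}

#' Generate a full synthetic two-test cohort
#'
#' Draws true parameters per participant, then runs two complete simulated
#' assessment sessions (via [run_session()]) per participant. Returns the
#' pooled trial logs and the participant-estimates table consumed by the
#' agreement suite. This is the end-to-end stand-in for a real two-test
#' study: between-test variability arises from the Psi procedure's own
#' estimation noise plus any configured truth jitter.
#'
#' @param spec A [cohort_spec()].
#' @param config A [session_config()] used for every session (its seed is
#'   re-derived per participant and test).
#' @param out_dir Optional directory; when given, per-session trial logs
#'   and the combined estimates CSV are written there.
#' @return List with `trials` (pooled tibble, extra columns
#'   `participant_id`, `test`), `estimates` (one row per participant), and
#'   `truths`.
#' @export
generate_cohort <- function(spec = cohort_spec(), config = session_config(),
                            out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "session_config"))
  truths <- cohort_truths(spec)
  all_trials <- list()
  est_rows <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    fits <- numeric(4)
    for (test in 1:2) {
      a <- if (test == 1) truths$alpha_test1[i] else truths$alpha_test2[i]
      b <- if (test == 1) truths$beta_test1[i] else truths$beta_test2[i]
      obs <- observer(a, b, seed = derive_seed(spec$seed, i * 17 + test))
      cfg <- config
      cfg$seed <- derive_seed(spec$seed, i * 31 + test * 7)
      sess <- run_session(cfg, obs)
      est <- psi_estimate(sess$state)
      fits[(test - 1) * 2 + 1:2] <- c(est$alpha, est$beta)
      trials <- dplyr::mutate(sess$trials,
                              participant_id = truths$participant_id[i],
                              test = test, .before = 1)
      all_trials[[length(all_trials) + 1]] <- trials
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        write_trial_log(sess$trials, file.path(
          out_dir, sprintf("%s_test%d_trials.csv", truths$participant_id[i], test)))
      }
    }
    est_rows[[i]] <- tibble::tibble(
      participant_id = truths$participant_id[i],
      pse_test1_mm = fits[1], unc_test1_mm = fits[2],
      pse_test2_mm = fits[3], unc_test2_mm = fits[4]
    )
  }
  estimates <- dplyr::bind_rows(est_rows)
  estimates <- estimates[, c("participant_id", "pse_test1_mm", "pse_test2_mm",
                             "unc_test1_mm", "unc_test2_mm")]
  if (!is.null(out_dir)) {
    write_estimates(estimates, file.path(out_dir, "participant_estimates.csv"))
  }
  list(trials = dplyr::bind_rows(all_trials), estimates = estimates,
       truths = truths)
}

#' Fast estimate-level cohort simulation
#'
#' Skips the trial-by-trial sessions and draws each test's PSE/uncertainty
#' estimate as truth plus independent estimation noise. The default noise
#' SDs are back-computed from the limits of agreement observed with the
#' human cohort (SD of the between-test difference divided by sqrt(2)):
#' about 6.8 mm for the PSE and 3.9 mm for the uncertainty. Useful for
#' calibration studies of the agreement suite where thousands of cohorts
#' are needed; [generate_cohort()] remains the full-pipeline reference.
#'
#' @param spec A [cohort_spec()].
#' @param est_noise_pse_sd,est_noise_unc_sd Per-test estimation noise SD, mm.
#' @return The participant-estimates tibble plus a `truths` attribute.
#' @export
simulate_estimates <- function(spec = cohort_spec(),
                               est_noise_pse_sd = 6.8,
                               est_noise_unc_sd = 3.9) {
  truths <- cohort_truths(spec)
  stream <- rng_stream(derive_seed(spec$seed, 997))
  n <- spec$n_participants
  noise <- with_stream(stream, stats::rnorm(4 * n))
  out <- tibble::tibble(
    participant_id = truths$participant_id,
    pse_test1_mm = truths$alpha_test1 + est_noise_pse_sd * noise[1:n],
    pse_test2_mm = truths$alpha_test2 + est_noise_pse_sd * noise[n + 1:n],
    unc_test1_mm = pmax(0.5, truths$beta_test1 + est_noise_unc_sd * noise[2 * n + 1:n]),
    unc_test2_mm = pmax(0.5, truths$beta_test2 + est_noise_unc_sd * noise[3 * n + 1:n])
  )
  attr(out, "truths") <- truths
  out
}

#' Redraw cohort responses with an injected movement-direction effect
#'
#' Keeps the stimulus/direction structure of logged cohort trials (so the
#' stimulus distribution is the one the adaptive protocol actually
#' produces) but replaces each response with a fresh Bernoulli draw whose
#' logit is the participant's psychometric logit plus `direction_effect`
#' on backward trials. With `direction_effect = 0` this is a plain
#' parametric redraw of stimulus-driven responses.
#'
#' @param trials Pooled cohort trials (from [generate_cohort()]`$trials`).
#' @param truths Cohort truth table (from [generate_cohort()]`$truths`).
#' @param direction_effect Logit-scale shift on backward trials.
#' @param seed Integer seed.
#' @return The trials tibble with redrawn `response`.
#' @export
inject_direction_effect <- function(trials, truths, direction_effect, seed = 1L) {
  stopifnot(all(c("participant_id", "stim_mm", "direction") %in% names(trials)),
            all(trials$participant_id %in% truths$participant_id))
  i <- match(trials$participant_id, truths$participant_id)
  p <- stats::plogis(
    stats::qlogis(stats::pnorm(trials$stim_mm, truths$alpha_true[i],
                               truths$beta_true[i])) +
      ifelse(trials$direction == "backward", direction_effect, 0)
  )
  u <- with_stream(rng_stream(seed), stats::runif(nrow(trials)))
  dplyr::mutate(trials, response = ifelse(u < p, "left", "right"))
}

#' Simulate direction-tagged trial data without the adaptive loop
#'
#' Generates pooled 2AFC trial data for the movement-direction analysis:
#' stimuli drawn uniformly from the stimulus set, balanced pseudorandom
#' directions, and responses from each participant's psychometric function,
#' optionally shifted by `direction_effect` (logit scale) on backward
#' trials. With `direction_effect = 0` the responses depend on the stimulus
#' only, so the fitted direction contrast should concentrate near zero.
#'
#' @param spec A [cohort_spec()] (truth distributions and seed).
#' @param n_trials_per_test Trials per participant per test.
#' @param n_tests Number of tests pooled; default 2.
#' @param direction_effect Logit-scale shift added on backward trials.
#' @param stimuli A [stimulus_set()].
#' @return Tibble with `participant_id`, `test`, `trial`, `stim_mm`,
#'   `direction`, `response`.
#' @export
simulate_direction_trials <- function(spec = cohort_spec(),
                                      n_trials_per_test = 75L,
                                      n_tests = 2L,
                                      direction_effect = 0,
                                      stimuli = stimulus_set()) {
  truths <- cohort_truths(spec)
  stream <- rng_stream(derive_seed(spec$seed, 4242))
  rows <- list()
  n <- as.integer(n_trials_per_test)
  for (i in seq_len(spec$n_participants)) {
    for (test in seq_len(n_tests)) {
      stim <- with_stream(stream, sample(as.numeric(stimuli), n, replace = TRUE))
      n_back <- ceiling(n / 2)
      dirs <- with_stream(stream, sample(c(rep("backward", n_back),
                                           rep("forward", n - n_back))))
      # direction effect injected on the logit scale of the response model
      p <- stats::plogis(stats::qlogis(stats::pnorm(stim, truths$alpha_true[i],
                                                    truths$beta_true[i])) +
                           ifelse(dirs == "backward", direction_effect, 0))
      u <- with_stream(stream, stats::runif(n))
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = truths$participant_id[i], test = test,
        trial = seq_len(n), stim_mm = stim, direction = dirs,
        response = ifelse(u < p, "left", "right")
      )
    }
  }
  dplyr::bind_rows(rows)
}
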