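#' Session configuration for the 75-trial assessment
#'
#' Encodes the full testing protocol: 75 trials per test; the test foot
#' starts in front of the stimulus (backward movement) on 38 trials and
#' behind it (forward movement) on 37; start positions are drawn from
#' Normal(+/-100 mm, 5 mm); the foot travels to the start at 40-50 mm/s and
#' to the stimulus at 10-30 mm/s (uniform); engagement stimuli are inserted
#' once per 10-trial block (far) and once per 5-trial block (near), never in
#' the first 5 trials; short breaks follow trials 25 and 50.
#'
#' @param n_trials Number of trials per test.
#' @param stimuli A [stimulus_set()].
#' @param grid A [psi_grid()] for the Psi posterior.
#' @param start_center Magnitude of the start-distribution centres, mm.
#' @param start_sd SD of the start distributions, mm.
#' @param start_speed_range,stimulus_speed_range Uniform speed ranges, mm/s.
#' @param far_period,near_period Block lengths for far/near insertions.
#' @param preselect_warmup No preselected stimuli at trials `<= warmup`.
#' @param break_trials Trials after which a walking break occurs (metadata
#'   only; breaks never touch the posterior).
#' @param baseline_offset Baseline marker difference, mm; subtracted (after
#'   rounding to the nearest mm) from imported hardware positions.
#' @param n_front_starts Number of in-front starts (backward movements).
#'   Default 38 when `n_trials` is 75, otherwise `ceiling(n_trials / 2)`.
#' @param pause_range Pause at the start position, s (logged only).
#' @param seed Integer seed driving all protocol-level randomness.
#' @return A `session_config` object.
#' @export
session_config <- function(n_trials = 75L,
                           stimuli = stimulus_set(),
                           grid = psi_grid(),
                           start_center = 100,
                           start_sd = 5,
                           start_speed_range = c(40, 50),
                           stimulus_speed_range = c(10, 30),
                           far_period = 10L,
                           near_period = 5L,
                           preselect_warmup = 5L,
                           break_trials = c(25L, 50L),
                           baseline_offset = 0,
                           n_front_starts = NULL,
                           pause_range = c(0, 2),
                           seed = 1L) {
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 1)
  if (is.null(n_front_starts)) {
    n_front_starts <- if (n_trials == 75L) 38L else as.integer(ceiling(n_trials / 2))
  }
  n_front_starts <- as.integer(n_front_starts)
  if (n_front_starts < 0 || n_front_starts > n_trials) {
    stop("`n_front_starts` must lie between 0 and `n_trials`", call. = FALSE)
  }
  check_range <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 2 || any(r <= 0) || r[1] >= r[2]) {
      stop(sprintf("`%s` must be positive with low < high", nm), call. = FALSE)
    }
  }
  check_range(start_speed_range, "start_speed_range")
  check_range(stimulus_speed_range, "stimulus_speed_range")
  stopifnot(start_sd > 0, start_center > 0,
            far_period >= 1, near_period >= 1, preselect_warmup >= 0)
  if (preselect_warmup >= n_trials) {
    stop("`preselect_warmup` must be smaller than `n_trials`", call. = FALSE)
  }
  stimuli <- if (inherits(stimuli, "stimulus_set")) stimuli else stimulus_set(stimuli)
  structure(
    list(n_trials = n_trials, stimuli = stimuli, grid = grid,
         start_center = as.numeric(start_center), start_sd = as.numeric(start_sd),
         start_speed_range = as.numeric(start_speed_range),
         stimulus_speed_range = as.numeric(stimulus_speed_range),
         far_period = as.integer(far_period), near_period = as.integer(near_period),
         preselect_warmup = as.integer(preselect_warmup),
         break_trials = as.integer(break_trials),
         baseline_offset = as.numeric(baseline_offset),
         n_front_starts = n_front_starts,
         pause_range = as.numeric(pause_range),
         seed = as.integer(seed)),
    class = "session_config"
  )
}

#' Pseudorandomized movement-direction sequence
#'
#' A uniformly random permutation with exactly `n_front_starts` in-front
#' starts ("backward" movement of the test foot to the stimulus) and
#' `n_trials - n_front_starts` behind starts ("forward").
#'
#' @param config A [session_config()].
#' @param stream An [rng_stream()].
#' @return Character vector of `"backward"` / `"forward"`, one per trial.
#' @export
plan_direction_sequence <- function(config, stream) {
  stopifnot(inherits(config, "session_config"))
  dirs <- c(rep("backward", config$n_front_starts),
            rep("forward", config$n_trials - config$n_front_starts))
  with_stream(stream, sample(dirs))
}

#' Sample a trial's start position
#'
#' Backward trials start in front: Normal(+start_center, start_sd); forward
#' trials start behind: Normal(-start_center, start_sd). Draws on the wrong
#' side of the stimulus are rejected and redrawn from the same distribution
#' until the movement direction is correct.
#'
#' @param direction `"backward"` or `"forward"`.
#' @param stimulus The trial's stimulus position, mm.
#' @param config A [session_config()].
#' @param stream An [rng_stream()].
#' @param max_redraws Redraw budget before signalling an error.
#' @return Start position, mm.
#' @export
sample_start_position <- function(direction, stimulus, config, stream,
                                  max_redraws = 1e4) {
  direction <- match.arg(direction, c("backward", "forward"))
  centre <- if (direction == "backward") config$start_center else -config$start_center
  for (i in seq_len(max_redraws)) {
    x <- with_stream(stream, stats::rnorm(1, centre, config$start_sd))
    ok <- if (direction == "backward") x > stimulus else x < stimulus
    if (ok) return(x)
  }
  stop(sprintf(
    "could not draw a %s start for stimulus %g mm in %g attempts; check the start distribution",
    direction, stimulus, max_redraws), call. = FALSE)
}

#' Schedule the preselected engagement stimuli
#'
#' Within each complete `far_period`-trial block one trial is replaced by a
#' far stimulus, and within each complete `near_period`-trial block one by a
#' near stimulus, both at uniformly random in-block positions; no
#' preselected stimulus may land in the first `preselect_warmup` trials.
#' When the far and near draws collide, the far insertion wins and the near
#' slot is redrawn within its block (a block whose only legal slots are
#' exhausted is skipped). All remaining trials are Psi-selected.
#'
#' @param config A [session_config()].
#' @param stream An [rng_stream()].
#' @return Character vector (`"psi"`, `"far"`, `"near"`), one per trial.
#' @export
schedule_preselected <- function(config, stream) {
  stopifnot(inherits(config, "session_config"))
  n <- config$n_trials
  source <- rep("psi", n)
  pick <- function(slots) {
    if (length(slots) == 0) return(NA_integer_)
    if (length(slots) == 1) return(slots)
    with_stream(stream, sample(slots, 1))
  }
  n_far_blocks <- n %/% config$far_period
  for (b in seq_len(n_far_blocks)) {
    slots <- ((b - 1) * config$far_period + 1):(b * config$far_period)
    slots <- slots[slots > config$preselect_warmup]
    i <- pick(slots)
    if (!is.na(i)) source[i] <- "far"
  }
  n_near_blocks <- n %/% config$near_period
  for (b in seq_len(n_near_blocks)) {
    slots <- ((b - 1) * config$near_period + 1):(b * config$near_period)
    slots <- slots[slots > config$preselect_warmup & source[slots] == "psi"]
    i <- pick(slots)
    if (!is.na(i)) source[i] <- "near"
  }
  source
}

#' Realise a preselected stimulus position
#'
#' Far stimuli are a uniform choice among the two outermost positions at
#' each end of the stimulus set (±90, ±100 mm for the default set). Near
#' stimuli sit at the current PSE estimate plus a uniform offset of ±10,
#' ±20 or ±30 mm, rounded to the nearest member of the stimulus set (ties
#' round away from zero) and clamped to its range.
#'
#' @param source `"far"` or `"near"`.
#' @param current_estimate Current [psychometric_params()] estimate.
#' @param config A [session_config()].
#' @param stream An [rng_stream()].
#' @return Stimulus position, mm.
#' @export
realize_preselected_stimulus <- function(source, current_estimate, config, stream) {
  source <- match.arg(source, c("far", "near"))
  stim <- as.numeric(config$stimuli)
  if (source == "far") {
    k <- length(stim)
    far_pool <- c(stim[1:2], stim[(k - 1):k])
    return(with_stream(stream, sample(far_pool, 1)))
  }
  current_estimate <- as_psychometric_params(current_estimate)
  offset <- with_stream(stream, sample(c(-30, -20, -10, 10, 20, 30), 1))
  snap_to_stimulus(current_estimate$alpha + offset, stim)
}

# Round to the nearest stimulus-set member; exact midpoints round away from
# zero; out-of-range targets clamp to the extremes.
snap_to_stimulus <- function(target, stimuli) {
  d <- abs(stimuli - target)
  best <- d <= min(d) + 1e-9
  cand <- stimuli[best]
  cand[order(-abs(cand), cand)][1L]
}

#' Baseline correction of hardware positions
#'
#' Participants' heels are aligned before the test, but a residual
#' anterior-posterior ankle-marker difference can remain; imported stimulus
#' positions and PSE estimates are corrected by subtracting this baseline
#' offset rounded to the nearest millimetre.
#'
#' @param raw_position Raw position(s), mm.
#' @param baseline_offset Baseline marker difference, mm.
#' @return Corrected position(s), mm.
#' @export
#' @examples
#' apply_baseline_correction(50, 3.4)
apply_baseline_correction <- function(raw_position, baseline_offset) {
  raw_position - round(baseline_offset)
}

#' Run one complete assessment session
#'
#' Executes the closed loop between the protocol and the Psi engine for
#' `config$n_trials` trials: source the stimulus (entropy-minimizing Psi
#' choice, or the scheduled far/near insertion), plan the movement
#' direction, start position and speeds, obtain the response, update the
#' joint posterior (preselected trials update it too), and record the
#' running estimates. Breaks after the configured trials are logged but by
#' construction cannot alter the posterior.
#'
#' @param config A [session_config()].
#' @param response_source Either an [observer()] or a function
#'   `function(stimulus, trial)` returning `"left"` or `"right"`.
#' @return A `psi_session`: list with the config, the trial tibble, the
#'   final `psi` state, and `estimates_at`, the running (alpha, beta)
#'   estimates recorded after trials 25/50/75 (those that exist) and the
#'   final trial.
#' @export
#' @examples
#' \donttest{
#' cfg <- session_config(n_trials = 10, grid = psi_grid(seq(-40, 40, 5), seq(5, 30, 5)))
#' s <- run_session(cfg, observer(12, 18, seed = 2))
#' s$trials
#' }
run_session <- function(config, response_source) {
  stopifnot(inherits(config, "session_config"))
  respond <- if (inherits(response_source, "observer")) {
    function(stimulus, trial) simulate_response(response_source, stimulus)
  } else if (is.function(response_source)) {
    response_source
  } else {
    stop("`response_source` must be an observer or a function", call. = FALSE)
  }

  protocol_stream <- rng_stream(config$seed)
  directions <- plan_direction_sequence(config, protocol_stream)
  sources <- schedule_preselected(config, protocol_stream)
  state <- psi_new(config$grid, config$stimuli)

  n <- config$n_trials
  checkpoints <- sort(unique(c(intersect(c(25L, 50L, 75L), seq_len(n)), n)))
  estimates_at <- list()
  col_start <- col_sspeed <- col_stim <- col_vspeed <- col_pause <-
    col_ahat <- col_bhat <- numeric(n)
  col_resp <- character(n)

  for (t in seq_len(n)) {
    src <- sources[t]
    stimulus <- if (src == "psi") {
      select_next_stimulus(state)
    } else {
      realize_preselected_stimulus(src, psi_estimate(state), config, protocol_stream)
    }
    direction <- directions[t]
    start <- sample_start_position(direction, stimulus, config, protocol_stream)
    speeds <- with_stream(protocol_stream, c(
      stats::runif(1, config$start_speed_range[1], config$start_speed_range[2]),
      stats::runif(1, config$stimulus_speed_range[1], config$stimulus_speed_range[2]),
      stats::runif(1, config$pause_range[1], config$pause_range[2])
    ))
    response <- respond(stimulus, t)
    if (!is.character(response) || !response %in% response_levels()) {
      stop(sprintf("response source returned an invalid response at trial %d", t),
           call. = FALSE)
    }
    state <- psi_update(state, stimulus, response)
    est <- psi_estimate(state)
    if (t %in% checkpoints) estimates_at[[as.character(t)]] <- est
    col_start[t] <- start
    col_sspeed[t] <- speeds[1]
    col_stim[t] <- stimulus
    col_vspeed[t] <- speeds[2]
    col_pause[t] <- speeds[3]
    col_resp[t] <- response
    col_ahat[t] <- est$alpha
    col_bhat[t] <- est$beta
  }

  trials <- tibble::tibble(
    trial = seq_len(n), source = sources, direction = directions,
    start_mm = col_start, start_speed_mm_s = col_sspeed,
    stim_mm = col_stim, stim_speed_mm_s = col_vspeed, pause_s = col_pause,
    response = col_resp, alpha_hat_mm = col_ahat, beta_hat_mm = col_bhat,
    break_after = seq_len(n) %in% config$break_trials
  )

  structure(
    list(config = config, trials = trials,
         state = state, estimates_at = estimates_at),
    class = "psi_session"
  )
}

#' @export
print.psi_session <- function(x, ...) {
  est <- psi_estimate(x$state)
  cat(sprintf("Assessment session: %d trials; final alpha-hat = %.1f mm, beta-hat = %.1f mm\n",
              x$config$n_trials, est$alpha, est$beta))
  for (nm in names(x$estimates_at)) {
    e <- x$estimates_at[[nm]]
    cat(sprintf("  after trial %s: alpha-hat = %.1f mm, beta-hat = %.1f mm\n",
                nm, e$alpha, e$beta))
  }
  invisible(x)
}

#' Replay a trial log through the Psi engine
#'
#' Re-applies the logged stimulus/response sequence to a fresh prior and
#' returns the per-trial estimates; with the session's own grid and stimulus
#' set this reproduces the logged `alpha_hat_mm` / `beta_hat_mm` exactly.
#'
#' @param trials A trial tibble (from [run_session()] or [read_trial_log()]).
#' @param grid A [psi_grid()] matching the one used to run the session.
#' @param stimuli A [stimulus_set()] matching the session's.
#' @return A tibble with `trial`, `alpha_hat_mm`, `beta_hat_mm`.
#' @export
replay_session <- function(trials, grid = psi_grid(), stimuli = stimulus_set()) {
  state <- psi_new(grid, stimuli)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    state <- psi_update(state, trials$stim_mm[i], trials$response[i])
    est <- psi_estimate(state)
    out[[i]] <- tibble::tibble(trial = trials$trial[i],
                               alpha_hat_mm = est$alpha,
                               beta_hat_mm = est$beta)
  }
  dplyr::bind_rows(out)
}
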