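test_that("direction sequences have the configured in-front/behind split", {
  cfg <- session_config()
  dirs <- plan_direction_sequence(cfg, rng_stream(1))
  expect_length(dirs, 75)
  expect_identical(sum(dirs == "backward"), 38L)
  expect_identical(sum(dirs == "forward"), 37L)

  # permutation property: both orderings of a 2-trial test occur
  cfg2 <- session_config(n_trials = 2, n_front_starts = 1, preselect_warmup = 0)
  firsts <- vapply(1:50, function(i) {
    plan_direction_sequence(cfg2, rng_stream(i))[1]
  }, character(1))
  expect_setequal(unique(firsts), c("backward", "forward"))

  expect_identical(plan_direction_sequence(cfg, rng_stream(9)),
                   plan_direction_sequence(cfg, rng_stream(9)))
  expect_error(session_config(n_trials = 10, n_front_starts = 11), "n_front_starts")
})

test_that("start positions land on the correct side with truncated-normal law", {
  cfg <- session_config()
  # backward start for a +90 stimulus: truncated Normal(100, 5) above 90
  draws <- vapply(1:2000, function(i) {
    sample_start_position("backward", 90, cfg, rng_stream(i))
  }, numeric(1))
  expect_true(all(draws > 90))
  a <- (90 - 100) / 5
  trunc_mean <- 100 + 5 * dnorm(a) / (1 - pnorm(a)) # analytic truncated mean
  expect_lt(abs(mean(draws) - trunc_mean), 0.5)

  # forward start below a -100 stimulus: left tail of Normal(-100, 5);
  # acceptance probability is exactly 1/2, accepted mean is the analytic
  # half-normal tail mean
  draws2 <- vapply(1:2000, function(i) {
    sample_start_position("forward", -100, cfg, rng_stream(i + 5000))
  }, numeric(1))
  expect_true(all(draws2 < -100))
  expect_lt(abs(mean(draws2) - (-100 - 5 * dnorm(0) / 0.5)), 0.5)

  # backward start far above the stimulus: effectively untruncated
  draws3 <- vapply(1:1000, function(i) {
    sample_start_position("backward", -100, cfg, rng_stream(i))
  }, numeric(1))
  expect_lt(abs(mean(draws3) - 100), 0.6)
})

test_that("preselected schedules obey warmup, block, and collision rules", {
  cfg <- session_config()
  for (i in 1:300) {
    src <- schedule_preselected(cfg, rng_stream(i))
    expect_length(src, 75)
    expect_true(all(src[1:5] == "psi")) # warmup
    for (b in 1:7) {
      expect_identical(sum(src[((b - 1) * 10 + 1):(b * 10)] == "far"), 1L)
    }
    near_per_block <- vapply(1:15, function(b) {
      sum(src[((b - 1) * 5 + 1):(b * 5)] == "near")
    }, integer(1))
    expect_identical(near_per_block[1], 0L)        # blocked by warmup
    expect_true(all(near_per_block[-1] == 1L))     # one per later block
  }

  # exhaustive small case: all legal slots occur, no illegal ones
  cfg10 <- session_config(n_trials = 10)
  far_slots <- integer(0)
  near_slots <- integer(0)
  for (i in 1:2000) {
    src <- schedule_preselected(cfg10, rng_stream(i))
    expect_true(all(src[1:5] == "psi"))
    expect_identical(sum(src == "far"), 1L)
    expect_lte(sum(src == "near"), 1L) # block 6-10 may be taken by far redraw
    far_slots <- union(far_slots, which(src == "far"))
    near_slots <- union(near_slots, which(src == "near"))
  }
  expect_setequal(far_slots, 6:10)
  expect_setequal(near_slots, 6:10)
})

test_that("preselected stimuli are realised as far extremes or snapped near offsets", {
  cfg <- session_config()
  far <- vapply(1:4000, function(i) {
    realize_preselected_stimulus("far", psychometric_params(0, 20), cfg, rng_stream(i))
  }, numeric(1))
  freqs <- table(far) / length(far)
  expect_setequal(as.numeric(names(freqs)), c(-100, -90, 90, 100))
  expect_true(all(abs(freqs - 0.25) < 0.03))

  near <- vapply(1:500, function(i) {
    realize_preselected_stimulus("near", psychometric_params(12, 18), cfg, rng_stream(i))
  }, numeric(1))
  # alpha-hat 12 + {±10, ±20, ±30} -> {-18, -8, 2, 22, 32, 42} -> snapped
  expect_setequal(sort(unique(near)), c(-20, -10, 0, 20, 30, 40))

  # rounding: 12 + 10 = 22 snaps to 20; midpoint ties round away from zero;
  # out-of-range targets clamp to the set's extremes
  s <- as.numeric(stimulus_set())
  expect_identical(propsi:::snap_to_stimulus(22, s), 20)
  expect_identical(propsi:::snap_to_stimulus(25, s), 30)
  expect_identical(propsi:::snap_to_stimulus(-25, s), -30)
  expect_identical(propsi:::snap_to_stimulus(125, s), 100)
  expect_identical(propsi:::snap_to_stimulus(95 + 30, s), 100)
})

test_that("baseline correction subtracts the offset rounded to the nearest mm", {
  expect_identical(apply_baseline_correction(50, 3.4), 47)
  expect_identical(apply_baseline_correction(50, 0), 50)
  expect_identical(apply_baseline_correction(-100, -2.6), -97)
})

test_that("sessions satisfy the protocol invariants trial by trial", {
  cfg <- fast_config(n_trials = 30, seed = 4)
  sess <- run_session(cfg, observer(10, 15, seed = 2))
  tr <- sess$trials
  expect_identical(nrow(tr), 30L)
  expect_identical(sum(tr$direction == "backward"), cfg$n_front_starts)
  # start side always consistent with the planned direction
  expect_true(all(ifelse(tr$direction == "backward",
                         tr$start_mm > tr$stim_mm, tr$start_mm < tr$stim_mm)))
  expect_true(all(tr$stim_mm %in% as.numeric(cfg$stimuli)))
  expect_true(all(tr$start_speed_mm_s >= 40 & tr$start_speed_mm_s <= 50))
  expect_true(all(tr$stim_speed_mm_s >= 10 & tr$stim_speed_mm_s <= 30))
  expect_true(all(tr$pause_s >= 0 & tr$pause_s <= 2))
  expect_identical(which(tr$break_after), c(25L))
})

test_that("sessions are deterministic and exactly replayable", {
  cfg <- fast_config(n_trials = 25, seed = 10)
  s1 <- run_session(cfg, observer(12, 18, seed = 6))
  s2 <- run_session(cfg, observer(12, 18, seed = 6))
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$estimates_at, s2$estimates_at)

  # replaying the log reproduces every recorded running estimate exactly
  rep <- replay_session(s1$trials, cfg$grid, cfg$stimuli)
  expect_identical(rep$alpha_hat_mm, s1$trials$alpha_hat_mm)
  expect_identical(rep$beta_hat_mm, s1$trials$beta_hat_mm)

  # a break is a metadata event: the posterior depends only on the
  # stimulus/response history, which replay just confirmed

  # n_trials = 25 records the single checkpoint at trial 25
  expect_identical(names(s1$estimates_at), "25")

  # different observer seed changes responses
  s3 <- run_session(cfg, observer(12, 18, seed = 7))
  expect_false(identical(s1$trials$response, s3$trials$response))
})

test_that("full sessions recover a typical observer within protocol tolerances", {
  # alpha 12 mm / beta 18 mm observer, study-scale grid. The package's
  # recovery study (200 sessions) put the joint 90% region of the absolute
  # errors inside +-8 mm for both parameters (marginal 90th percentiles
  # ~5.6 mm alpha, ~6.0 mm beta); assert that coverage with a binomial
  # margin for the 100 replicates run here.
  n_rep <- 100
  grid <- study_grid()
  errs <- t(vapply(seq_len(n_rep), function(i) {
    cfg <- session_config(grid = grid, seed = 1000 + i)
    s <- run_session(cfg, observer(12, 18, seed = 2000 + i))
    est <- psi_estimate(s$state)
    c(a = abs(est$alpha - 12), b = abs(est$beta - 18))
  }, numeric(2)))
  expect_gte(mean(errs[, "a"] < 8 & errs[, "b"] < 8), 0.88)
})

test_that("configuration validation rejects impossible protocols", {
  expect_error(session_config(start_speed_range = c(50, 40)), "low < high")
  expect_error(session_config(preselect_warmup = 80), "preselect_warmup")
  expect_error(run_session(fast_config(5), "not a responder"), "observer or a function")
  # a response function that returns garbage is caught at the trial
  expect_error(run_session(fast_config(5), function(s, t) "maybe"), "invalid response")
})
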