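test_that("hdi finds the narrowest window and matches exhaustive search", {
  # uniform 1..1000: any width-949 window works; tie broken at lowest start
  h <- hdi(1:1000, 0.95)
  expect_identical(unname(h), c(1, 950))

  # large standard-normal sample: close to the analytic +-1.96
  set.seed(1)
  z <- rnorm(2e5)
  h2 <- hdi(z)
  expect_lt(abs(h2["lower"] + 1.96), 0.05)
  expect_lt(abs(h2["upper"] - 1.96), 0.05)

  for (i in 1:25) {
    set.seed(i)
    x <- switch(1 + i %% 3,
                rnorm(500), rexp(500), c(rnorm(250, -4), rnorm(250, 4)))
    expect_equal(unname(hdi(x)), oracle_hdi(x), tolerance = 1e-12)
  }
  expect_error(hdi(c(1, NA, 2)))
})

test_that("pct_in_rope counts closed-interval membership exactly", {
  expect_identical(pct_in_rope(c(-0.2, 0, 0.4), c(-0.5, 0.5)), 100)
  x <- c(1, 1, 2, 3, 1)
  expect_identical(pct_in_rope(x, c(1, 1)), 100 * 3 / 5) # degenerate rope
  set.seed(2)
  y <- rnorm(1000)
  expect_equal(pct_in_rope(y, c(-1, 0.3)),
               100 * sum(y >= -1 & y <= 0.3) / 1000)
})

test_that("the conjugate normal posterior is exact and seed-stable", {
  set.seed(3)
  y <- rnorm(40, 5, 2)
  d1 <- sample_normal_posterior(y, sampler_config(5000, 2, seed = 9))
  d2 <- sample_normal_posterior(y, sampler_config(5000, 2, seed = 9))
  expect_identical(d1$mu, d2$mu)
  # flat prior: posterior mean of mu equals the sample mean (within MC error)
  expect_lt(abs(mean(d1$mu) - mean(y)), 4 * sd(y) / sqrt(length(y)) / sqrt(100))
  # posterior sd of mu ~ s/sqrt(n)
  expect_lt(abs(sd(d1$mu) - sd(y) / sqrt(40)), 0.1)
  # zero-variance data: degenerate point mass, flagged
  d3 <- sample_normal_posterior(rep(2, 5), sampler_config(100, 1))
  expect_true(attr(d3, "degenerate"))
  expect_true(all(d3$mu == 2))
})

test_that("the conjugate regression posterior recovers the least-squares fit", {
  set.seed(4)
  x <- runif(60, -20, 40)
  y <- 3 + 0.5 * x + rnorm(60, 0, 2)
  d <- sample_regression_posterior(x, y, sampler_config(5000, 2, seed = 1))
  ols <- lm(y ~ x)
  expect_lt(abs(mean(d$slope) - coef(ols)[2]), 0.02)
  expect_lt(abs(mean(d$intercept) - coef(ols)[1]), 0.35)
  # frequentist-matching spread under the flat prior
  expect_lt(abs(sd(d$slope) - summary(ols)$coefficients[2, 2]), 0.01)
  d0 <- sample_regression_posterior(rep(1, 5), 1:5, sampler_config(100, 1))
  expect_true(attr(d0, "degenerate"))
})

test_that("identical test administrations give perfect agreement", {
  est <- fixture_estimates(6)
  est$pse_test2_mm <- est$pse_test1_mm
  ba <- bland_altman(est, "pse", sampler_config(2000, 2, seed = 1))
  expect_identical(ba$loa_low, 0)
  expect_identical(ba$loa_high, 0)
  expect_true(ba$loa_collapsed)
  s <- ba$summaries
  expect_identical(s$pct_in_rope[s$term == "mean_bias"], 100)
  expect_true(good_agreement(ba))

  rr <- test_retest_regression(est, "pse", sampler_config(2000, 2, seed = 1))
  expect_equal(rr$summaries$mean[rr$summaries$term == "slope"], 1, tolerance = 1e-10)
  expect_equal(rr$summaries$mean[rr$summaries$term == "intercept"], 0,
               tolerance = 1e-8)
})

test_that("limits of agreement are order-invariant and antisymmetric in test roles", {
  est <- fixture_estimates(8, bias = 2, noise = 3, seed = 5)
  ba <- bland_altman(est, "pse", sampler_config(500, 1, seed = 1))
  perm <- est[sample(nrow(est)), ]
  ba_perm <- bland_altman(perm, "pse", sampler_config(500, 1, seed = 1))
  expect_equal(c(ba$loa_low, ba$loa_high), c(ba_perm$loa_low, ba_perm$loa_high))

  swapped <- est
  swapped$pse_test1_mm <- est$pse_test2_mm
  swapped$pse_test2_mm <- est$pse_test1_mm
  ba_sw <- bland_altman(swapped, "pse", sampler_config(500, 1, seed = 1))
  expect_equal(ba_sw$loa_low, -ba$loa_high, tolerance = 1e-12)
  expect_equal(ba_sw$loa_high, -ba$loa_low, tolerance = 1e-12)
})

test_that("an injected constant bias is recovered by the mean-bias posterior", {
  # cohorts built with a -3.3 mm PSE bias; recovered posterior means stay
  # within +-1.5 mm of the injected value on average
  recovered <- vapply(1:20, function(i) {
    est <- simulate_estimates(cohort_spec(injected_mean_bias = -3.3, seed = i))
    ba <- bland_altman(est, "pse", sampler_config(2000, 1, seed = i))
    ba$summaries$mean[ba$summaries$term == "mean_bias"]
  }, numeric(1))
  expect_lt(abs(mean(recovered) - (-3.3)), 1.5)
})

test_that("an injected proportional bias is recovered by the regression posterior", {
  slopes <- numeric(10)
  ropes <- numeric(10)
  for (i in 1:10) {
    est <- simulate_estimates(cohort_spec(injected_slope_bias = 0.3, seed = i),
                              est_noise_pse_sd = 2, est_noise_unc_sd = 2)
    ba <- bland_altman(est, "pse", sampler_config(2000, 1, seed = i))
    slopes[i] <- ba$summaries$mean[ba$summaries$term == "slope"]
    ropes[i] <- ba$summaries$pct_in_rope[ba$summaries$term == "slope"]
  }
  expect_lt(abs(mean(slopes) - 0.3), 0.1)
  expect_lt(mean(ropes), 10)
})

test_that("ICC(2,1) matches the ANOVA oracle and its boundary cases", {
  est <- fixture_estimates(6)
  est$pse_test2_mm <- est$pse_test1_mm
  expect_equal(icc_2_1(est, "pse")$icc, 1)

  # hand-built 4 x 2 table, checked against aov() mean squares
  tab <- tibble::tibble(
    participant_id = c("a", "b", "c", "d"),
    pse_test1_mm = c(10, 14, 2, 30),
    pse_test2_mm = c(12, 11, 6, 26),
    unc_test1_mm = c(10, 10, 10, 10),
    unc_test2_mm = c(10, 10, 10, 10)
  )
  long <- data.frame(
    y = c(tab$pse_test1_mm, tab$pse_test2_mm),
    subj = factor(rep(tab$participant_id, 2)),
    test = factor(rep(1:2, each = 4))
  )
  ms <- summary(aov(y ~ subj + test, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 4; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_2_1(tab, "pse")$icc, icc_oracle, tolerance = 1e-12)

  # independent tests: ICC centers near zero
  iccs <- vapply(1:30, function(i) {
    set.seed(i)
    t <- tibble::tibble(participant_id = as.character(1:12),
                        pse_test1_mm = rnorm(12), pse_test2_mm = rnorm(12),
                        unc_test1_mm = rexp(12) + 1, unc_test2_mm = rexp(12) + 1)
    icc_2_1(t, "pse")$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs)), 0.15)

  # fully constant table: variance components vanish
  flat <- tibble::tibble(participant_id = c("a", "b", "c"),
                         pse_test1_mm = 1, pse_test2_mm = 1,
                         unc_test1_mm = 1, unc_test2_mm = 1)
  out <- icc_2_1(flat, "pse")
  expect_true(out$degenerate)
  expect_true(is.nan(out$icc))
})

test_that("the agreement decision rule rejects only decisive bias evidence", {
  # unbiased, low-noise cohort: good agreement
  est <- fixture_estimates(10, bias = 0, noise = 2, seed = 2)
  expect_true(good_agreement(bland_altman(est, "pse", sampler_config(2000, 1, seed = 1))))
  # gross bias: >= 90% of the mean-bias posterior outside +-5 mm
  est_bad <- fixture_estimates(10, bias = 15, noise = 2, seed = 2)
  expect_false(good_agreement(bland_altman(est_bad, "pse", sampler_config(2000, 1, seed = 1))))
  expect_error(bland_altman(fixture_estimates(2), "pse"), "at least 3")
})

test_that("test-retest regression recovers known coefficients and runs at n = 3", {
  set.seed(8)
  est <- fixture_estimates(13, seed = 8)
  est$unc_test1_mm <- runif(13, 8, 30)
  est$unc_test2_mm <- 0.65 * est$unc_test1_mm + 5.6 + rnorm(13, 0, 1)
  rr <- test_retest_regression(est, "uncertainty", sampler_config(4000, 2, seed = 3))
  expect_lt(abs(rr$summaries$mean[rr$summaries$term == "slope"] - 0.65), 0.12)

  tiny <- fixture_estimates(3, noise = 1, seed = 4)
  rr3 <- test_retest_regression(tiny, "pse", sampler_config(2000, 1, seed = 1))
  s3 <- rr3$summaries[rr3$summaries$term == "slope", ]
  expect_gt(s3$hdi_high - s3$hdi_low, 0.2) # wide HDI at minimal n
})
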