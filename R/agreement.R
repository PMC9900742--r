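measure_columns <- function(measure = c("pse", "uncertainty")) {
  measure <- match.arg(measure)
  if (measure == "pse") c("pse_test1_mm", "pse_test2_mm")
  else c("unc_test1_mm", "unc_test2_mm")
}

check_estimates <- function(estimates, measure, min_n = 3L) {
  cols <- measure_columns(measure)
  missing <- setdiff(c("participant_id", cols), names(estimates))
  if (length(missing) > 0) {
    stop("estimates table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(estimates) < min_n) {
    stop(sprintf("at least %d participants are required (got %d)",
                 min_n, nrow(estimates)), call. = FALSE)
  }
  list(test1 = estimates[[cols[1]]], test2 = estimates[[cols[2]]])
}

#' Bayesian Bland-Altman agreement analysis
#'
#' Assesses test-retest agreement of the PSE or uncertainty estimates from
#' two administrations of the assessment. Three components: (1) closed-form
#' limits of agreement, `mean(diff) +/- 1.96 * sd(diff)` where
#' `diff = Test1 - Test2`; (2) the posterior of the mean bias `mu` in
#' `diff_i ~ Normal(mu, sigma)`, with ROPE ±5 mm; (3) the posterior of the
#' slope and intercept of the regression of `diff` on the "true" score
#' (the per-participant mean of the two tests), with ROPEs ±0.1 and ±5 mm.
#'
#' @param estimates Tibble with columns `participant_id`, `pse_test1_mm`,
#'   `pse_test2_mm`, `unc_test1_mm`, `unc_test2_mm` (see
#'   [read_estimates()]).
#' @param measure `"pse"` or `"uncertainty"`.
#' @param sampler A [sampler_config()].
#' @param rope_mean,rope_slope,rope_intercept ROPE intervals.
#' @return A `bland_altman` object: tibble of posterior summaries (`term`
#'   in `mean_bias`, `slope`, `intercept`), limits of agreement, the raw
#'   differences/true scores, and the posterior draws.
#' @export
#' @examples
#' est <- tibble::tibble(participant_id = sprintf("P%02d", 1:6),
#'                       pse_test1_mm = c(5, 10, 18, 2, 25, 12),
#'                       pse_test2_mm = c(7, 9, 15, 4, 24, 14),
#'                       unc_test1_mm = c(15, 18, 22, 12, 19, 25),
#'                       unc_test2_mm = c(14, 20, 21, 15, 18, 22))
#' ba <- bland_altman(est, "pse", sampler_config(2000, 2, seed = 1))
#' tidy(ba)
bland_altman <- function(estimates, measure = c("pse", "uncertainty"),
                         sampler = sampler_config(),
                         rope_mean = c(-5, 5), rope_slope = c(-0.1, 0.1),
                         rope_intercept = c(-5, 5)) {
  measure <- match.arg(measure)
  d <- check_estimates(estimates, measure)
  diffs <- d$test1 - d$test2
  true_score <- (d$test1 + d$test2) / 2

  sd_diff <- stats::sd(diffs)
  loa <- c(low = mean(diffs) - 1.96 * sd_diff, high = mean(diffs) + 1.96 * sd_diff)
  collapsed <- sd_diff < .Machine$double.eps

  mean_cfg <- sampler
  reg_cfg <- sampler
  reg_cfg$seed <- derive_seed(sampler$seed, 101)
  mean_draws <- sample_normal_posterior(diffs, mean_cfg)
  reg_draws <- sample_regression_posterior(true_score, diffs, reg_cfg)

  summaries <- dplyr::bind_rows(
    dplyr::mutate(posterior_summary(mean_draws$mu, rope_mean), term = "mean_bias"),
    dplyr::mutate(posterior_summary(reg_draws$slope, rope_slope), term = "slope"),
    dplyr::mutate(posterior_summary(reg_draws$intercept, rope_intercept), term = "intercept")
  )
  summaries <- dplyr::relocate(summaries, "term")

  structure(
    list(measure = measure, n = length(diffs),
         loa_low = unname(loa["low"]), loa_high = unname(loa["high"]),
         loa_collapsed = collapsed,
         summaries = summaries,
         data = tibble::tibble(participant_id = estimates$participant_id,
                               test1 = d$test1, test2 = d$test2,
                               diff = diffs, true_score = true_score),
         draws = list(mean_bias = mean_draws$mu, slope = reg_draws$slope,
                      intercept = reg_draws$intercept)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (%s, n = %d)\n", x$measure, x$n))
  cat(sprintf("  limits of agreement: %.1f to %.1f mm%s\n", x$loa_low, x$loa_high,
              if (x$loa_collapsed) " [zero-variance differences: limits collapsed]" else ""))
  print(x$summaries)
  invisible(x)
}

#' Agreement decision rule
#'
#' A measure is declared to be in "good agreement" unless at least
#' `threshold`% of the mass of any Bland-Altman posterior (mean bias,
#' bias-regression slope, bias-regression intercept) falls outside its
#' ROPE — i.e. unless some posterior provides decisive evidence of a bias.
#'
#' @param ba A [bland_altman()] result.
#' @param threshold Percentage of posterior mass outside the ROPE that
#'   triggers rejection; default 90.
#' @return Logical.
#' @export
good_agreement <- function(ba, threshold = 90) {
  stopifnot(inherits(ba, "bland_altman"))
  all(100 - ba$summaries$pct_in_rope < threshold)
}

#' Bayesian test-retest regression
#'
#' Regression of the Test 2 estimate on the Test 1 estimate,
#' `Test2_i ~ Normal(b + m * Test1_i, sigma)`. Perfect agreement corresponds
#' to slope 1 and intercept 0 (stored as `reference`); the slope/intercept
#' HDIs characterise how plausible that is.
#'
#' @inheritParams bland_altman
#' @return A `retest_regression` object with posterior summaries for
#'   `slope` and `intercept`.
#' @export
test_retest_regression <- function(estimates, measure = c("pse", "uncertainty"),
                                   sampler = sampler_config()) {
  measure <- match.arg(measure)
  d <- check_estimates(estimates, measure)
  draws <- sample_regression_posterior(d$test1, d$test2, sampler)
  summaries <- dplyr::bind_rows(
    dplyr::mutate(posterior_summary(draws$slope), term = "slope"),
    dplyr::mutate(posterior_summary(draws$intercept), term = "intercept")
  )
  structure(
    list(measure = measure, n = length(d$test1),
         summaries = dplyr::relocate(summaries, "term"),
         reference = c(slope = 1, intercept = 0),
         data = tibble::tibble(test1 = d$test1, test2 = d$test2),
         draws = list(slope = draws$slope, intercept = draws$intercept)),
    class = "retest_regression"
  )
}

#' @export
print.retest_regression <- function(x, ...) {
  cat(sprintf("Test-retest regression (%s, n = %d); perfect agreement = slope 1, intercept 0\n",
              x$measure, x$n))
  print(x$summaries)
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the standard ANOVA decomposition of the participants-by-tests table,
#' with the conventional F-based confidence interval (Satterthwaite
#' degrees of freedom for the lower/upper bounds).
#'
#' @inheritParams bland_altman
#' @param conf_level Confidence level for the interval; default 0.95.
#' @return A one-row tibble: `measure`, `icc`, `ci_low`, `ci_high`, `n`,
#'   `k`, `degenerate` (TRUE when variance components vanish and the ICC is
#'   undefined).
#' @export
icc_2_1 <- function(estimates, measure = c("pse", "uncertainty"),
                    conf_level = 0.95) {
  measure <- match.arg(measure)
  d <- check_estimates(estimates, measure)
  x <- cbind(d$test1, d$test2)
  n <- nrow(x)
  k <- ncol(x)

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    return(tibble::tibble(measure = measure, icc = NaN, ci_low = NaN,
                          ci_high = NaN, n = n, k = k, degenerate = TRUE))
  }
  icc <- (msr - mse) / denom

  alpha_level <- 1 - conf_level
  if (mse < .Machine$double.eps && msc < .Machine$double.eps) {
    # no within-participant variability at all: ICC is exactly 1
    return(tibble::tibble(measure = measure, icc = icc, ci_low = 1, ci_high = 1,
                          n = n, k = k, degenerate = FALSE))
  }
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha_level / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha_level / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  tibble::tibble(measure = measure, icc = icc, ci_low = ci_low,
                 ci_high = ci_high, n = n, k = k, degenerate = FALSE)
}
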