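#' Full agreement report
#'
#' Runs the complete inference suite on a participant-estimates table (and
#' optionally the pooled trial logs): Bland-Altman limits of agreement,
#' mean-bias and bias-versus-true-score posteriors, test-retest regression,
#' and ICC(2,1) for both the PSE and the uncertainty, plus the
#' movement-direction logistic model when trial data are supplied.
#'
#' @param estimates Participant-estimates tibble (see [read_estimates()]).
#' @param trials Optional pooled trial tibble with `participant_id`,
#'   `stim_mm`, `direction`, `response` for the direction analysis.
#' @param sampler A [sampler_config()].
#' @param rope_mean,rope_slope,rope_intercept ROPEs passed to
#'   [bland_altman()].
#' @param rope_direction ROPE for the direction contrast.
#' @return An `agreement_report` object (a list of fitted components).
#' @export
agreement_report <- function(estimates, trials = NULL,
                             sampler = sampler_config(),
                             rope_mean = c(-5, 5), rope_slope = c(-0.1, 0.1),
                             rope_intercept = c(-5, 5),
                             rope_direction = c(-0.5, 0.5)) {
  components <- list()
  for (measure in c("pse", "uncertainty")) {
    s_ba <- sampler; s_ba$seed <- derive_seed(sampler$seed, match(measure, c("pse", "uncertainty")))
    s_rr <- sampler; s_rr$seed <- derive_seed(sampler$seed, 10 + match(measure, c("pse", "uncertainty")))
    components[[measure]] <- list(
      bland_altman = bland_altman(estimates, measure, s_ba, rope_mean,
                                  rope_slope, rope_intercept),
      retest = test_retest_regression(estimates, measure, s_rr),
      icc = icc_2_1(estimates, measure)
    )
  }
  direction <- NULL
  if (!is.null(trials)) {
    direction <- fit_direction_logistic(trials, sampler, rope_direction)
  }
  structure(list(measures = components, direction = direction,
                 n_participants = nrow(estimates)),
            class = "agreement_report")
}

report_measure_row <- function(name, comp) {
  ba <- comp$bland_altman
  s <- function(term) ba$summaries[ba$summaries$term == term, ]
  r <- function(term) comp$retest$summaries[comp$retest$summaries$term == term, ]
  tibble::tibble(
    measure = name,
    loa_low_mm = ba$loa_low, loa_high_mm = ba$loa_high,
    mean_bias_mm = s("mean_bias")$mean,
    mean_bias_hdi_low = s("mean_bias")$hdi_low,
    mean_bias_hdi_high = s("mean_bias")$hdi_high,
    mean_bias_pct_in_rope = s("mean_bias")$pct_in_rope,
    bias_slope = s("slope")$mean,
    bias_slope_hdi_low = s("slope")$hdi_low,
    bias_slope_hdi_high = s("slope")$hdi_high,
    bias_slope_pct_in_rope = s("slope")$pct_in_rope,
    bias_intercept_mm = s("intercept")$mean,
    bias_intercept_hdi_low = s("intercept")$hdi_low,
    bias_intercept_hdi_high = s("intercept")$hdi_high,
    bias_intercept_pct_in_rope = s("intercept")$pct_in_rope,
    retest_slope = r("slope")$mean,
    retest_slope_hdi_low = r("slope")$hdi_low,
    retest_slope_hdi_high = r("slope")$hdi_high,
    retest_intercept_mm = r("intercept")$mean,
    retest_intercept_hdi_low = r("intercept")$hdi_low,
    retest_intercept_hdi_high = r("intercept")$hdi_high,
    icc = comp$icc$icc, icc_ci_low = comp$icc$ci_low,
    icc_ci_high = comp$icc$ci_high,
    good_agreement = good_agreement(ba)
  )
}

#' Tabular view of an agreement report
#'
#' One row per measure with the limits of agreement, the Bland-Altman
#' posteriors (mean bias, bias-regression slope/intercept, each with HDI
#' and % in ROPE), the test-retest regression, the ICC(2,1) with CI, and
#' the good-agreement decision.
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.agreement_report <- function(x, ...) {
  dplyr::bind_rows(
    report_measure_row("pse", x$measures$pse),
    report_measure_row("uncertainty", x$measures$uncertainty)
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

#' Human-readable agreement report
#'
#' @param report An [agreement_report()].
#' @return Character vector of report lines.
#' @export
format_report_text <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  fmt_s <- function(s, unit = "") {
    sprintf("%.2f%s [%.2f %.2f]%s", s$mean, unit, s$hdi_low, s$hdi_high,
            if (is.na(s$pct_in_rope)) "" else sprintf(" (%.1f%% in ROPE)", s$pct_in_rope))
  }
  lines <- c(sprintf("Agreement report (n = %d participants)", report$n_participants))
  for (m in c("pse", "uncertainty")) {
    comp <- report$measures[[m]]
    ba <- comp$bland_altman
    g <- function(term) ba$summaries[ba$summaries$term == term, ]
    r <- function(term) comp$retest$summaries[comp$retest$summaries$term == term, ]
    lines <- c(
      lines,
      sprintf("== %s ==", toupper(m)),
      sprintf("  Limits of agreement: %.1f to %.1f mm", ba$loa_low, ba$loa_high),
      sprintf("  Mean bias: %s", fmt_s(g("mean_bias"), " mm")),
      sprintf("  Bias regression: slope %s; intercept %s",
              fmt_s(g("slope")), fmt_s(g("intercept"), " mm")),
      sprintf("  Test1 vs Test2 regression: slope %s; intercept %s",
              fmt_s(r("slope")), fmt_s(r("intercept"), " mm")),
      sprintf("  ICC(2,1): %.2f [%.2f, %.2f]", comp$icc$icc, comp$icc$ci_low,
              comp$icc$ci_high),
      sprintf("  Good agreement: %s", ifelse(good_agreement(ba), "yes", "no"))
    )
  }
  if (!is.null(report$direction)) {
    d <- report$direction
    s <- d$summaries[d$summaries$term == "contrast", ]
    lines <- c(lines, "== Movement direction ==",
               sprintf("  Backward - forward contrast: %s", fmt_s(s)))
  }
  lines
}

#' Machine-readable agreement report
#'
#' Serialises the full report (summaries, ROPEs, diagnostics, decisions)
#' as JSON.
#'
#' @param report An [agreement_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  payload <- list(
    n_participants = report$n_participants,
    measures = lapply(report$measures, function(comp) list(
      limits_of_agreement = list(low_mm = comp$bland_altman$loa_low,
                                 high_mm = comp$bland_altman$loa_high,
                                 collapsed = comp$bland_altman$loa_collapsed),
      bland_altman = comp$bland_altman$summaries,
      test_retest_regression = comp$retest$summaries,
      icc_2_1 = comp$icc,
      good_agreement = good_agreement(comp$bland_altman)
    )),
    direction = if (is.null(report$direction)) NULL else list(
      summaries = report$direction$summaries,
      diagnostics = report$direction$diagnostics
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
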