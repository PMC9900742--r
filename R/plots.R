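#' Plot a psychometric function
#'
#' Draws the cumulative-Gaussian probability of a "left" judgement against
#' foot-position difference, optionally overlaying observed per-stimulus
#' response proportions (dot size proportional to trial count).
#'
#' @param params A [psychometric_params()].
#' @param trials Optional trial tibble with `stim_mm` and `response`.
#' @param range Stimulus range to draw, mm.
#' @return A ggplot.
#' @export
plot_psychometric <- function(params, trials = NULL, range = c(-100, 100)) {
  params <- as_psychometric_params(params)
  curve_df <- tibble::tibble(
    stim_mm = seq(range[1], range[2], length.out = 201),
    p_left = psychometric_prob(params, seq(range[1], range[2], length.out = 201))
  )
  p <- ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$stim_mm, y = .data$p_left)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = params$alpha, linetype = "dashed") +
    ggplot2::labs(x = "Foot position difference (mm; + = left forward)",
                  y = "P(judged left more forward)") +
    ggplot2::theme_minimal()
  if (!is.null(trials)) {
    obs <- dplyr::summarise(
      dplyr::group_by(trials, .data$stim_mm),
      p_left = mean(.data$response == "left"), n = dplyr::n(), .groups = "drop")
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(size = .data$n), alpha = 0.6) +
      ggplot2::scale_size_area(max_size = 4)
  }
  p
}

#' Session trajectory plot
#'
#' Stimulus placements and running parameter estimates over trials, faceted
#' into stimulus track (coloured by source) and the evolving alpha/beta
#' estimates.
#'
#' @param object A [run_session()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psi_session <- function(object, ...) {
  tr <- object$trials
  long <- dplyr::bind_rows(
    tibble::tibble(trial = tr$trial, value = tr$stim_mm, panel = "stimulus (mm)",
                   source = tr$source),
    tibble::tibble(trial = tr$trial, value = tr$alpha_hat_mm,
                   panel = "alpha-hat (mm)", source = "estimate"),
    tibble::tibble(trial = tr$trial, value = tr$beta_hat_mm,
                   panel = "beta-hat (mm)", source = "estimate")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value)) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$panel == "stimulus (mm)"),
                        ggplot2::aes(colour = .data$source), size = 1.2) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$panel != "stimulus (mm)")) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Trial", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Per-participant Test1 - Test2 differences against the per-participant
#' mean of the two tests, with the limits of agreement (dotted), the zero
#' line (dashed), and the most probable bias-regression line.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- function(term) object$summaries[object$summaries$term == term, ]
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$true_score, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted") +
    ggplot2::geom_abline(intercept = s("intercept")$mean,
                         slope = s("slope")$mean, colour = "steelblue") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("Mean of Test 1 and Test 2 (%s, mm)", object$measure),
      y = "Test 1 - Test 2 (mm)") +
    ggplot2::theme_minimal()
}

#' Test-retest regression plot
#'
#' @param object A [test_retest_regression()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.retest_regression <- function(object, ...) {
  s <- function(term) object$summaries[object$summaries$term == term, ]
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$test1, y = .data$test2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(intercept = s("intercept")$mean,
                         slope = s("slope")$mean, colour = "steelblue") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = sprintf("Test 1 (%s, mm)", object$measure),
                  y = sprintf("Test 2 (%s, mm)", object$measure)) +
    ggplot2::theme_minimal()
}
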