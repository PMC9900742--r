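#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of a Bland-Altman fit
#'
#' @param x A [bland_altman()] result.
#' @param ... Unused.
#' @return Tibble with one row per term (`mean_bias`, `slope`,
#'   `intercept`): posterior mean, 95% HDI, % in ROPE, ROPE bounds.
#' @export
tidy.bland_altman <- function(x, ...) {
  dplyr::mutate(x$summaries, measure = x$measure, .before = 1)
}

#' One-row summary of a Bland-Altman fit
#'
#' @param x A [bland_altman()] result.
#' @param ... Unused.
#' @return Tibble: measure, n, limits of agreement, mean bias, and the
#'   good-agreement decision.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, n = x$n,
    loa_low_mm = x$loa_low, loa_high_mm = x$loa_high,
    mean_bias_mm = x$summaries$mean[x$summaries$term == "mean_bias"],
    good_agreement = good_agreement(x)
  )
}

#' @rdname tidy.bland_altman
#' @export
tidy.retest_regression <- function(x, ...) {
  dplyr::mutate(x$summaries, measure = x$measure, .before = 1)
}

#' @rdname tidy.bland_altman
#' @export
tidy.direction_fit <- function(x, ...) x$summaries

#' One-row summary of the direction-effect fit
#'
#' @param x A [fit_direction_logistic()] result.
#' @param ... Unused.
#' @return Tibble with the contrast mean, HDI, % in ROPE, and diagnostics.
#' @export
glance.direction_fit <- function(x, ...) {
  s <- x$summaries[x$summaries$term == "contrast", ]
  tibble::tibble(
    contrast_mean = s$mean, hdi_low = s$hdi_low, hdi_high = s$hdi_high,
    pct_in_rope = s$pct_in_rope,
    rhat = x$diagnostics$rhat, ess = x$diagnostics$ess,
    n_trials = x$n_trials, n_participants = x$n_participants
  )
}

#' Per-trial view of a session
#'
#' @param x A [run_session()] result.
#' @param ... Unused.
#' @return The trial tibble.
#' @export
tidy.psi_session <- function(x, ...) x$trials

#' One-row summary of a session
#'
#' @param x A [run_session()] result.
#' @param ... Unused.
#' @return Tibble with the number of trials and the running estimates at
#'   the recorded checkpoints.
#' @export
glance.psi_session <- function(x, ...) {
  est <- psi_estimate(x$state)
  out <- tibble::tibble(n_trials = x$config$n_trials,
                        alpha_hat_mm = est$alpha, beta_hat_mm = est$beta)
  for (nm in names(x$estimates_at)) {
    out[[paste0("alpha_hat_", nm, "_mm")]] <- x$estimates_at[[nm]]$alpha
    out[[paste0("beta_hat_", nm, "_mm")]] <- x$estimates_at[[nm]]$beta
  }
  out
}
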