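#' Sampler configuration
#'
#' Defaults mirror the inference setup used for the human agreement
#' analyses: 10,000 posterior draws in each of 4 chains with 2,000 tuning
#' iterations per chain. The conjugate samplers for the normal-mean and
#' regression models ignore `n_tune` (they draw exactly from the posterior);
#' the MCMC logistic model uses all three.
#'
#' @param n_draws Posterior draws per chain.
#' @param n_chains Number of chains.
#' @param n_tune Tuning (adaptation + burn-in) iterations per chain.
#' @param seed Integer seed.
#' @return A `sampler_config` object.
#' @export
sampler_config <- function(n_draws = 10000L, n_chains = 4L, n_tune = 2000L,
                           seed = 1L) {
  stopifnot(n_draws >= 1, n_chains >= 1, n_tune >= 0)
  structure(list(n_draws = as.integer(n_draws), n_chains = as.integer(n_chains),
                 n_tune = as.integer(n_tune), seed = as.integer(seed)),
            class = "sampler_config")
}

#' Posterior draws for a normal mean model
#'
#' Bayesian model `y_i ~ Normal(mu, sigma)` under the noninformative
#' reference prior `p(mu, sigma^2) proportional to 1/sigma^2` — the
#' wide-prior limit of a maximum-entropy Normal/half-flat specification.
#' The posterior is available in closed form (`sigma^2` scaled-inverse-chi
#' squared, `mu | sigma^2` normal), so draws are exact, not MCMC. With all
#' `y` identical the posterior degenerates to a point mass; this is flagged
#' via the `"degenerate"` attribute rather than treated as an error.
#'
#' @param y Numeric data vector, length >= 2.
#' @param sampler A [sampler_config()].
#' @return Tibble of draws with columns `mu`, `sigma`; attribute
#'   `degenerate` (logical).
#' @export
sample_normal_posterior <- function(y, sampler = sampler_config()) {
  stopifnot(is.numeric(y), length(y) >= 2, all(is.finite(y)))
  n <- length(y)
  ybar <- mean(y)
  s2 <- stats::var(y)
  ndraw <- sampler$n_draws * sampler$n_chains
  stream <- rng_stream(sampler$seed)
  if (s2 < .Machine$double.eps) {
    out <- tibble::tibble(mu = rep(ybar, ndraw), sigma = rep(0, ndraw))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  draws <- with_stream(stream, {
    sigma2 <- (n - 1) * s2 / stats::rchisq(ndraw, df = n - 1)
    mu <- stats::rnorm(ndraw, ybar, sqrt(sigma2 / n))
    list(mu = mu, sigma = sqrt(sigma2))
  })
  out <- tibble::tibble(mu = draws$mu, sigma = draws$sigma)
  attr(out, "degenerate") <- FALSE
  out
}

#' Posterior draws for a simple linear regression
#'
#' Bayesian model `y_i ~ Normal(b + m * x_i, sigma)` under the reference
#' prior `p(b, m, sigma^2) proportional to 1/sigma^2`; exact
#' normal-inverse-chi-squared draws (no MCMC). Degenerate designs (constant
#' `x`) are flagged.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param sampler A [sampler_config()].
#' @return Tibble of draws with columns `intercept`, `slope`, `sigma`;
#'   attribute `degenerate`.
#' @export
sample_regression_posterior <- function(x, y, sampler = sampler_config()) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3, all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  X <- cbind(1, x)
  XtX <- crossprod(X)
  ndraw <- sampler$n_draws * sampler$n_chains
  if (abs(det(XtX)) < 1e-10 || stats::var(x) < .Machine$double.eps) {
    out <- tibble::tibble(intercept = rep(mean(y), ndraw),
                          slope = rep(0, ndraw), sigma = rep(0, ndraw))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  XtX_inv <- solve(XtX)
  beta_hat <- drop(XtX_inv %*% crossprod(X, y))
  resid <- y - drop(X %*% beta_hat)
  df <- n - 2
  s2 <- sum(resid^2) / df
  stream <- rng_stream(sampler$seed)
  R <- chol(XtX_inv)
  draws <- with_stream(stream, {
    sigma2 <- if (s2 < .Machine$double.eps) rep(0, ndraw) else df * s2 / stats::rchisq(ndraw, df = df)
    z <- matrix(stats::rnorm(2 * ndraw), ncol = 2)
    betas <- sweep((z %*% R) * sqrt(sigma2), 2, beta_hat, "+")
    list(b = betas[, 1], m = betas[, 2], sigma = sqrt(sigma2))
  })
  out <- tibble::tibble(intercept = draws$b, slope = draws$m, sigma = draws$sigma)
  attr(out, "degenerate") <- FALSE
  out
}
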