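#' Highest density interval of a sample
#'
#' The narrowest contiguous window containing `prob` of the draws, found by
#' scanning all windows of the required size over the sorted sample (ties
#' broken at the lowest start). For multimodal posteriors this still returns
#' a single contiguous interval, which may be wider than the union of HPD
#' regions.
#'
#' @param samples Numeric vector of posterior draws (>= 2 finite values).
#' @param prob Mass to cover; default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hdi(rnorm(1e4))
hdi <- function(samples, prob = 0.95) {
  samples <- as.numeric(samples)
  stopifnot(all(is.finite(samples)), length(samples) >= 2,
            prob > 0, prob <= 1)
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- 1:(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths) # which.min takes the first (lowest start) on ties
  c(lower = x[i], upper = x[i + m - 1])
}

#' Percentage of draws inside a region of practical equivalence
#'
#' @param samples Numeric vector of posterior draws.
#' @param rope Length-2 interval `c(low, high)` with `low <= high`; the
#'   interval is closed.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' pct_in_rope(rnorm(1e4), c(-0.5, 0.5))
pct_in_rope <- function(samples, rope) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 1, all(is.finite(samples)),
            is.numeric(rope), length(rope) == 2, rope[1] <= rope[2])
  100 * mean(samples >= rope[1] & samples <= rope[2])
}

#' Summarise a posterior sample
#'
#' Mean, 95% HDI, and (when a ROPE is supplied) the percentage of draws in
#' the ROPE.
#'
#' @param samples Numeric vector of posterior draws.
#' @param rope Optional ROPE interval.
#' @param prob HDI mass; default 0.95.
#' @return A one-row tibble: `mean`, `hdi_low`, `hdi_high`, `pct_in_rope`
#'   (NA without a ROPE), `rope_low`, `rope_high`.
#' @export
posterior_summary <- function(samples, rope = NULL, prob = 0.95) {
  h <- hdi(samples, prob)
  tibble::tibble(
    mean = mean(samples),
    hdi_low = unname(h[1]),
    hdi_high = unname(h[2]),
    pct_in_rope = if (is.null(rope)) NA_real_ else pct_in_rope(samples, rope),
    rope_low = if (is.null(rope)) NA_real_ else rope[1],
    rope_high = if (is.null(rope)) NA_real_ else rope[2]
  )
}
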