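#' Whole-series descriptive statistics
#'
#' The 12-value whole-series block: mean, standard deviation (population
#' form, `sqrt(mean((x - xbar)^2))`), the three quartiles (linear
#' interpolation between order statistics, quantile type 7), kurtosis,
#' interquartile range, skewness, and four residual/volatility summaries
#' taken from an AR(1)+GARCH(1,1) fit: `rss` (sum of squared deviations of
#' the series from its conditional mean), `resstd` (standard deviation of
#' the residual series), `volmean` and `volstd` (mean and standard
#' deviation of the conditional volatility).
#'
#' Kurtosis defaults to the raw moment-ratio form
#' `sum((x - xbar)^4) / ((N - 1) * sigma^4)`, which is approximately 3 for
#' a normal sample; set `excess_kurtosis` in the config to subtract 3.
#' Skewness uses the analogous `sum(...^3) / ((N - 1) * sigma^3)`.
#'
#' @param w A [waveform()] or numeric vector, length >= 4.
#' @param garch An optional [fit_garch()] result for this very series; if
#'   omitted one is fitted (with the rolling-sd fallback on degenerate
#'   input).
#' @param config An [sfx_config()] (controls the excess-kurtosis flag and
#'   the GARCH iteration budget).
#' @return A one-row tibble with columns `mean, std, q1, q2, q3, kurtosis,
#'   iqr, skewness, rss, resstd, volmean, volstd`.
#' @examples
#' descriptive_stats(rnorm(500))
#' @export
descriptive_stats <- function(w, garch = NULL, config = sfx_config()) {
  x <- as_samples(w)
  n <- length(x)
  if (n < 4) stop("series too short for descriptive statistics (need >= 4)",
                  call. = FALSE)
  if (is.null(garch)) {
    garch <- fit_garch_safe(x, ar_order = 1, maxiter = config$garch_maxiter)
  }
  if (garch$n != n) {
    stop("the garch fit was not computed on this series (length mismatch)",
         call. = FALSE)
  }
  m <- mean(x)
  sigma <- sqrt(mean((x - m)^2))
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  kurt <- if (sigma > 0) sum((x - m)^4) / ((n - 1) * sigma^4) else 0
  if (config$excess_kurtosis) kurt <- kurt - 3
  skew <- if (sigma > 0) sum((x - m)^3) / ((n - 1) * sigma^3) else 0

  e <- garch$residuals
  v <- garch$volatility
  fit_rng <- seq.int(n - length(e) + 1L, n)
  tibble::tibble(
    mean = m, std = sigma, q1 = q[1], q2 = q[2], q3 = q[3],
    kurtosis = kurt, iqr = q[3] - q[1], skewness = skew,
    rss = sum((x[fit_rng] - garch$fitted)^2),
    resstd = sqrt(mean((e - mean(e))^2)),
    volmean = mean(v),
    volstd = sqrt(mean((v - mean(v))^2))
  )
}
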