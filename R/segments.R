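#' Partition a series into equal contiguous segments
#'
#' Splits the series into `n_seg` contiguous, non-overlapping, ordered
#' pieces.  When the length is not divisible, the first
#' `length %% n_seg` segments are one sample longer (balanced remainder).
#'
#' @param w A [waveform()] or numeric vector.
#' @param n_seg Number of segments (>= 1, <= series length).
#' @return A list of `n_seg` numeric vectors.
#' @examples
#' lengths(segment(1:101, 20))  # first segment gets the extra sample
#' @export
segment <- function(w, n_seg = 20) {
  x <- as_samples(w)
  n_seg <- as.integer(n_seg)
  if (n_seg < 1) stop("n_seg must be >= 1", call. = FALSE)
  n <- length(x)
  if (n < n_seg) {
    stop("series of length ", n, " cannot be cut into ", n_seg, " segments",
         call. = FALSE)
  }
  lens <- rep(n %/% n_seg, n_seg)
  extra <- n %% n_seg
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(s, e) x[s:e])
}

#' Trend and volatility statistics of one segment
#'
#' Fits the ordinary least squares line `s(t) = beta * t + alpha + e(t)`
#' with `t = 0..n-1` and summarises the segment by its gradient (`beta`),
#' intercept, residual sum of squares, residual standard deviation
#' (population form), and the mean and standard deviation of the
#' conditional volatility of a constant-mean GARCH(1,1) model fitted to
#' the OLS residuals.  Degenerate segments (constant, or GARCH
#' non-convergence) take the rolling-sd fallback; a perfectly linear
#' segment yields zero rss, resstd, volmean and volstd.
#'
#' @param seg Numeric vector, length >= 4.
#' @param config An [sfx_config()].
#' @return One-row tibble: `gradient, intercept, rss, resstd, volmean,
#'   volstd` (the intercept is reported but is not part of the 5-value
#'   piecewise feature block).
#' @export
segment_features <- function(seg, config = sfx_config()) {
  x <- as_samples(seg)
  n <- length(x)
  if (n < 4) stop("segment too short (need >= 4 points)", call. = FALSE)
  t <- 0:(n - 1)
  tc <- t - mean(t)
  beta <- sum(tc * x) / sum(tc^2)
  alpha <- mean(x) - beta * mean(t)
  e <- x - (alpha + beta * t)
  rss <- sum(e^2)
  resstd <- sqrt(mean((e - mean(e))^2))
  if (resstd == 0) {
    volmean <- 0
    volstd <- 0
  } else {
    g <- fit_garch_safe(e, ar_order = 0, maxiter = config$garch_maxiter)
    v <- g$volatility
    volmean <- mean(v)
    volstd <- sqrt(mean((v - mean(v))^2))
  }
  tibble::tibble(gradient = beta, intercept = alpha, rss = rss,
                 resstd = resstd, volmean = volmean, volstd = volstd)
}

#' Piecewise feature block of a waveform
#'
#' Applies [segment()] then [segment_features()] and flattens the result
#' into the `5 * n_seg` named values `grad_1..grad_n, rss_1..rss_n,
#' resstd_*, volmean_*, volstd_*` (statistic-major order, matching the
#' conventional piecewise feature table).
#'
#' @param w A [waveform()] or numeric vector.
#' @param config An [sfx_config()] (uses `n_seg`).
#' @return Named numeric vector of length `5 * n_seg`.
#' @export
piecewise_features <- function(w, config = sfx_config()) {
  segs <- segment(as_samples(w), config$n_seg)
  feats <- purrr::map_dfr(segs, segment_features, config = config)
  idx <- seq_len(config$n_seg)
  out <- c(feats$gradient, feats$rss, feats$resstd, feats$volmean,
           feats$volstd)
  names(out) <- c(paste0("grad_", idx), paste0("rss_", idx),
                  paste0("resstd_", idx), paste0("volmean_", idx),
                  paste0("volstd_", idx))
  out
}
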