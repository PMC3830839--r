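#' Recommended linear prediction order
#'
#' The predictor order follows the speech-processing rule of thumb
#' `p = round(sample_rate / 1000) + gamma`, where `gamma` (2 or 3)
#' compensates for glottal roll-off and gives the predictor some
#' flexibility beyond the formant poles.  At 10 kHz this gives 12-13.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param gamma Compensation term, conventionally 2 or 3.
#' @return Integer predictor order.
#' @examples
#' lpc_order(10000, 2)  # 12
#' @export
lpc_order <- function(sample_rate, gamma = 2) {
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive", call. = FALSE)
  }
  as.integer(round(sample_rate / 1000) + gamma)
}

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Autocorrelation at lags 0..p via FFT (O(n log n)); biased estimator,
# which keeps the Toeplitz system positive semidefinite.
autocorr <- function(x, p) {
  n <- length(x)
  m <- stats::nextn(2L * n, 2)
  X <- fft(c(x, numeric(m - n)))
  ac <- Re(fft(X * Conj(X), inverse = TRUE)) / m
  ac[seq_len(p + 1)] / n
}

#' Fit a linear prediction (all-pole) model
#'
#' Models each sample as a linear combination of its `p` predecessors:
#' `x_hat(n) = sum_i a_i x(n - i)`.  A Hamming taper is applied to the full
#' series, autocorrelations at lags `0..p` are computed, and the
#' Yule-Walker normal equations are solved by the Levinson-Durbin
#' recursion.  The gain satisfies `G^2 = R(0) - sum_i a_i R(i)` (the final
#' prediction-error energy), clipped at zero.
#'
#' @param w A [waveform()] or numeric vector, length `> p`, not constant.
#' @param p Predictor order (see [lpc_order()]).
#' @return An object of class `lpc_model` with elements `order`,
#'   `coefficients` (`a_1..a_p`), `gain`, and `window = "hamming"`.
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = c(0.75, -0.5)), 5000))
#' coef(compute_lpc(x, 2))
#' @export
compute_lpc <- function(w, p) {
  x <- as_samples(w)
  p <- as.integer(p)
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  if (length(x) <= p) stop("series must be longer than p", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate signal: constant or zero series has no LPC model",
         call. = FALSE)
  }
  xw <- x * hamming_window(length(x))
  r <- autocorr(xw, p)
  if (r[1] <= 0 || !all(is.finite(r))) {
    stop("degenerate signal: autocorrelation is singular", call. = FALSE)
  }
  ld <- levinson_durbin(r, p)
  structure(
    list(order = p, coefficients = ld$a, gain = sqrt(max(ld$e, 0)),
         window = "hamming", reflection = ld$k),
    class = "lpc_model"
  )
}

# Levinson-Durbin recursion for the Yule-Walker system R a = r.
# Returns predictor coefficients a (sign convention: x_hat = sum a_i x(n-i)),
# final prediction error e, and reflection coefficients k.
levinson_durbin <- function(r, p) {
  a <- numeric(p)
  k <- numeric(p)
  e <- r[1]
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[seq_len(i - 1)] * r[i:2])
    if (e <= .Machine$double.eps * r[1]) {
      stop("singular Toeplitz system at order ", i,
           " (prediction error collapsed to zero)", call. = FALSE)
    }
    k[i] <- acc / e
    a_new <- a
    a_new[i] <- k[i]
    if (i > 1) {
      a_new[seq_len(i - 1)] <- a[seq_len(i - 1)] - k[i] * a[(i - 1):1]
    }
    a <- a_new
    e <- e * (1 - k[i]^2)
  }
  list(a = a, e = e, k = k)
}

#' @export
coef.lpc_model <- function(object, ...) object$coefficients

#' @export
print.lpc_model <- function(x, ...) {
  cat(sprintf("<lpc_model> order %d, gain %.4g, %s window\n",
              x$order, x$gain, x$window))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Convert LPC coefficients to cepstral coefficients
#'
#' Uses the standard recursion from predictor coefficients `a_n` to the
#' cepstrum of the fitted all-pole spectrum:
#' `c_1 = a_1` and, for `1 < n <= n_cc`,
#' `c_n = a_n + (1/n) * sum_{k=1}^{n-1} k * c_k * a_{n-k}`.
#' The zeroth coefficient `c_0 = ln G` is computed but excluded from the
#' default feature vector (the canonical frequency block has 10
#' coefficients); set `include_c0 = TRUE` to prepend it.
#'
#' @param model An [compute_lpc()] fit.
#' @param n_cc Number of cepstral coefficients (default 10, `<= order`).
#' @param include_c0 Prepend `c_0 = ln(gain)`.
#' @return Named numeric vector `cc_1..cc_n` (plus `cc_0` if requested),
#'   with `ln G` attached as attribute `c0`.
#' @export
lpc_to_cc <- function(model, n_cc = 10, include_c0 = FALSE) {
  stopifnot(inherits(model, "lpc_model"))
  n_cc <- as.integer(n_cc)
  if (n_cc > model$order) {
    stop("n_cc must not exceed the LPC order (", model$order, ")",
         call. = FALSE)
  }
  a <- model$coefficients
  cc <- numeric(n_cc)
  cc[1] <- a[1]
  if (n_cc > 1) {
    for (n in 2:n_cc) {
      k <- seq_len(n - 1)
      cc[n] <- a[n] + sum(k * cc[k] * a[n - k]) / n
    }
  }
  names(cc) <- paste0("cc_", seq_len(n_cc))
  c0 <- if (model$gain > 0) log(model$gain) else -Inf
  if (include_c0) cc <- c(cc_0 = c0, cc)
  attr(cc, "c0") <- c0
  cc
}

#' Frequency-domain feature block of a waveform
#'
#' Convenience wrapper: fit the LPC model at the order implied by the
#' sample rate (or an explicit override) and return the cepstral vector.
#'
#' @param w A [waveform()].
#' @param config An [sfx_config()].
#' @return Named numeric vector of length `config$n_cc`.
#' @export
cepstral_features <- function(w, config = sfx_config()) {
  stopifnot(inherits(w, "waveform"))
  p <- if (is.null(config$lpc_order)) {
    lpc_order(w$sample_rate, config$gamma)
  } else {
    config$lpc_order
  }
  lpc_to_cc(compute_lpc(w, p), n_cc = config$n_cc,
            include_c0 = config$include_c0)
}
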