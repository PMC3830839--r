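#' Fit an AR(1) mean + GARCH(1,1) variance model
#'
#' Gaussian maximum likelihood for
#' `X_t = mu + phi * X_{t-1} + e_t`,
#' `sigma_t^2 = omega + alpha * e_{t-1}^2 + beta * sigma_{t-1}^2`.
#' The variance recursion is initialised at the unconditional variance
#' `omega / (1 - alpha - beta)`.  Parameters are optimised on an
#' unconstrained scale that enforces `omega > 0`, `alpha, beta >= 0` and
#' `alpha + beta < 1`, with fixed deterministic starting values, so the fit
#' is reproducible.  The residual series `e_t` and conditional volatility
#' `sigma_t` are the raw material for the residual/volatility features.
#'
#' @param x Numeric series, length >= 50, non-constant.
#' @param ar_order Mean-equation order: 1 (default, AR(1)) or 0 (constant
#'   mean, used on detrended segments).
#' @param maxiter Optimiser iteration budget.
#' @return An object of class `garch_fit`: `coefficients`
#'   (`mu, phi, omega, alpha, beta`), `residuals` (e_t), `volatility`
#'   (sigma_t), `fitted` (conditional mean), `loglik`, `converged`, `n`.
#'   The residual/volatility series have length `n - ar_order`.
#' @examples
#' x <- simulate_garch(800, 0.1, 0.1, 0.8, seed = 1)
#' glance(fit_garch(x, ar_order = 0))
#' @export
fit_garch <- function(x, ar_order = 1, maxiter = 500) {
  x <- as_samples(x)
  n <- length(x)
  if (n < 50) stop("series too short for GARCH fitting (need >= 50)",
                   call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate series: constant input has no GARCH model",
         call. = FALSE)
  }
  ar_order <- as.integer(ar_order)
  stopifnot(ar_order %in% c(0L, 1L))

  # theta = (mu, z_phi, log omega, z_pers, z_frac); phi = tanh(z_phi),
  # persistence s = plogis(z_pers), alpha = s * plogis(z_frac).
  nll <- function(theta) {
    p <- decode_garch_theta(theta, ar_order)
    if (!all(is.finite(c(p$mu, p$phi, p$omega, p$alpha, p$beta)))) {
      return(1e10)
    }
    garch_nll_cpp(x, p$mu, p$phi, p$omega, p$alpha, p$beta, ar_order)
  }

  v0 <- stats::var(x)
  phi0 <- if (ar_order == 1L) {
    r <- stats::cor(x[-1], x[-n])
    max(min(r, 0.95), -0.95)
  } else 0
  start <- c(mean(x) * (1 - phi0),
             if (ar_order == 1L) atanh(phi0) else NULL,
             log(v0 * 0.1),
             stats::qlogis(0.9),    # persistence alpha + beta = 0.9
             stats::qlogis(1 / 9))  # alpha / (alpha + beta) = 1/9
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = maxiter, reltol = 1e-10))
  opt <- optim(opt$par, nll, method = "Nelder-Mead",
               control = list(maxit = maxiter, reltol = 1e-10))

  p <- decode_garch_theta(opt$par, ar_order)
  e <- garch_mean_resid(x, p, ar_order)
  s2 <- garch_sigma2(e, p)
  fitted <- if (ar_order == 1L) p$mu + p$phi * x[-n] else rep(p$mu, n)
  converged <- opt$convergence == 0 && all(is.finite(unlist(p))) &&
    p$alpha + p$beta < 1 && p$omega > 0
  structure(
    list(coefficients = c(mu = p$mu, phi = p$phi, omega = p$omega,
                          alpha = p$alpha, beta = p$beta),
         residuals = e, volatility = sqrt(s2), fitted = fitted,
         loglik = -opt$value, converged = converged, n = n,
         ar_order = ar_order),
    class = "garch_fit"
  )
}

decode_garch_theta <- function(theta, ar_order) {
  i <- 1L
  mu <- theta[i]; i <- i + 1L
  phi <- if (ar_order == 1L) { v <- tanh(theta[i]); i <- i + 1L; v } else 0
  omega <- exp(theta[i]); i <- i + 1L
  pers <- stats::plogis(theta[i]); i <- i + 1L
  frac <- stats::plogis(theta[i])
  list(mu = mu, phi = phi, omega = omega,
       alpha = pers * frac, beta = pers * (1 - frac))
}

garch_mean_resid <- function(x, p, ar_order) {
  if (ar_order == 1L) x[-1] - p$mu - p$phi * x[-length(x)] else x - p$mu
}

# sigma_t^2 recursion, vectorised through stats::filter.
garch_sigma2 <- function(e, p) {
  m <- length(e)
  s2_1 <- p$omega / (1 - p$alpha - p$beta)
  if (m == 1L) return(s2_1)
  rest <- stats::filter(p$omega + p$alpha * e[-m]^2, p$beta,
                        method = "recursive", init = s2_1)
  c(s2_1, as.numeric(rest))
}

#' Rolling-window fallback for degenerate series
#'
#' When ML estimation is unusable (constant segment, non-convergence on a
#' pathological input) the pipeline falls back to model-free surrogates:
#' residuals are the mean-detrended series and "volatility" is a rolling
#' standard deviation (window 20, minimum 5 points).  A constant series
#' yields all-zero residuals and volatility.
#'
#' @param x Numeric series.
#' @param window,min_points Rolling window size and minimum window.
#' @return A `garch_fit`-shaped object with `converged = FALSE` and
#'   `fallback = TRUE`.
#' @export
garch_fallback <- function(x, window = 20, min_points = 5) {
  x <- as_samples(x)
  e <- x - mean(x)
  n <- length(e)
  if (all(e == 0) || n < min_points) {
    vol <- numeric(n)
  } else {
    half <- window %/% 2L
    cs <- c(0, cumsum(e))
    cs2 <- c(0, cumsum(e^2))
    lo <- pmax(1L, seq_len(n) - half)
    hi <- pmin(n, seq_len(n) + half)
    width <- hi - lo + 1L
    short <- width < min_points        # edge windows fall back to the head
    lo[short] <- 1L
    hi[short] <- min(n, min_points)
    width <- hi - lo + 1L
    s1 <- cs[hi + 1L] - cs[lo]
    s2 <- cs2[hi + 1L] - cs2[lo]
    v <- (s2 - s1^2 / width) / pmax(width - 1L, 1L)
    vol <- sqrt(pmax(v, 0))
    vol[!is.finite(vol)] <- 0
  }
  structure(
    list(coefficients = c(mu = mean(x), phi = 0, omega = NA_real_,
                          alpha = NA_real_, beta = NA_real_),
         residuals = e, volatility = vol, fitted = rep(mean(x), n),
         loglik = NA_real_, converged = FALSE, n = n, ar_order = 0L,
         fallback = TRUE),
    class = "garch_fit"
  )
}

# Fit with automatic fallback; never throws on degenerate input.
fit_garch_safe <- function(x, ar_order = 1, maxiter = 500) {
  x <- as_samples(x)
  if (length(x) < 50 || stats::sd(x) == 0) return(garch_fallback(x))
  res <- tryCatch(fit_garch(x, ar_order = ar_order, maxiter = maxiter),
                  error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$volatility))) {
    return(garch_fallback(x))
  }
  res
}

#' @export
print.garch_fit <- function(x, ...) {
  cat(sprintf("<garch_fit> AR(%d)+GARCH(1,1), n = %d, %s\n",
              x$ar_order, x$n,
              if (isTRUE(x$fallback)) "rolling-sd fallback"
              else if (x$converged) "converged" else "NOT converged"))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_garch
#' @param x A `garch_fit` object (for `tidy`/`glance`).
#' @param ... Unused.
#' @export
tidy.garch_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_garch
#' @export
glance.garch_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, ar_order = x$ar_order, loglik = x$loglik,
    converged = x$converged, fallback = isTRUE(x$fallback),
    persistence = unname(x$coefficients["alpha"] + x$coefficients["beta"]),
    mean_volatility = mean(x$volatility)
  )
}
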