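# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: brute-force enumeration, textbook
# formulas, FFT identities.

# DTW by exhaustive warping-path enumeration (branch and bound), feasible
# for lengths <= 8.
bf_dtw <- function(x, y) {
  n <- length(x)
  m <- length(y)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(x[i] - y[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# Real cepstrum of the fitted all-pole (minimum-phase) spectrum via FFT;
# for n > 0 the complex cepstrum of a minimum-phase system is twice the
# real cepstrum.
fft_lpc_cepstrum <- function(a, gain, n_cc, nfft = 65536) {
  k <- seq_along(a)
  w <- 2 * pi * (0:(nfft - 1)) / nfft
  A <- 1 - vapply(w, function(wi) sum(a * exp(-1i * wi * k)), complex(1))
  lc <- log(Mod(gain / A))
  ce <- Re(fft(lc, inverse = TRUE)) / nfft
  2 * ce[2:(n_cc + 1)]
}

# Type-7 quantile by explicit sort-and-interpolate.
bf_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Textbook chi-square over an observed contingency table.
bf_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Plain-table entropy / MI / SU on discrete codes (nats).
bf_entropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log(p))
}
bf_mi <- function(x, y) {
  bf_entropy(x) + bf_entropy(y) - bf_entropy(paste(x, y))
}
bf_su <- function(x, y) {
  hx <- bf_entropy(x)
  hy <- bf_entropy(y)
  if (hx + hy == 0) 0 else 2 * bf_mi(x, y) / (hx + hy)
}

# CFS merit of a feature subset from discretised data.
bf_cfs_merit <- function(xd, yd, subset) {
  k <- length(subset)
  rcf <- mean(vapply(subset, function(j) bf_su(xd[, j], yd), numeric(1)))
  rff <- if (k == 1) 0 else {
    pr <- combn(subset, 2)
    mean(vapply(seq_len(ncol(pr)), function(p) {
      bf_su(xd[, pr[1, p]], xd[, pr[2, p]])
    }, numeric(1)))
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# Trapezoidal area under the empirical ROC curve.
bf_trapezoid_auc <- function(scores, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[positive] >= t),
                     numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!positive] >= t),
                     numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
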