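#' Multilevel Haar wavelet decomposition
#'
#' Orthonormal Haar analysis: at each level the approximation is split into
#' pairwise sums and differences scaled by `1/sqrt(2)`, so energy is
#' preserved (Parseval).  Odd-length approximations are extended by
#' repeating their last sample before pairing.
#'
#' @param x Numeric vector, length `>= 2^level`.
#' @param level Decomposition depth.
#' @return A list with `approx` (coarsest approximation) and `details`
#'   (list of detail vectors, coarsest level first).
#' @export
haar_dwt <- function(x, level = 3) {
  x <- as_samples(x)
  level <- as.integer(level)
  if (level < 1) stop("level must be >= 1", call. = FALSE)
  if (length(x) < 2^level) {
    stop("series of length ", length(x), " is too short for level ", level,
         call. = FALSE)
  }
  details <- vector("list", level)
  approx <- x
  for (l in seq_len(level)) {
    if (length(approx) %% 2L == 1L) approx <- c(approx, approx[length(approx)])
    odd <- approx[seq(1, length(approx), by = 2)]
    even <- approx[seq(2, length(approx), by = 2)]
    details[[l]] <- (odd - even) / sqrt(2)
    approx <- (odd + even) / sqrt(2)
  }
  # store coarsest first so subband index 1 = coarsest detail
  list(approx = approx, details = rev(details))
}

#' Top-k Haar wavelet coefficient features
#'
#' The wavelet baseline encoder: decompose at `level` (default 3), pool the
#' approximation and all detail coefficients, and keep the `k` (default 50)
#' largest by absolute value, returned in descending magnitude order and
#' zero-padded if fewer than `k` coefficients exist.  Ties in magnitude are
#' broken by coarser subband first (approximation, then coarse-to-fine
#' details), then by position, so the output is deterministic.
#'
#' @param w A [waveform()] or numeric vector.
#' @param level Decomposition level.
#' @param k Number of retained coefficients.
#' @return Named numeric vector `haar_1..haar_k`.
#' @export
haar_features <- function(w, level = 3, k = 50) {
  dec <- haar_dwt(as_samples(w), level = level)
  bands <- c(list(dec$approx), dec$details)  # subband 1 = approximation
  coefs <- unlist(bands, use.names = FALSE)
  band_idx <- rep(seq_along(bands), lengths(bands))
  pos_idx <- unlist(lapply(bands, seq_along), use.names = FALSE)
  ord <- order(-abs(coefs), band_idx, pos_idx)
  top <- coefs[ord][seq_len(min(k, length(coefs)))]
  if (length(top) < k) top <- c(top, numeric(k - length(top)))
  names(top) <- paste0("haar_", seq_len(k))
  top
}
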