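#' Dynamic time warping distance
#'
#' Elastic alignment distance between two sequences: the minimal cumulative
#' `|x_i - y_j|` cost over all warping paths satisfying the boundary,
#' monotonicity and continuity constraints (full window, no normalisation).
#' `dtw(x, x) = 0` and the distance is symmetric.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Non-negative scalar distance.
#' @examples
#' dtw(c(1, 2, 3), c(1, 2, 2, 3))  # 0: warping absorbs the repeat
#' @export
dtw <- function(x, y) {
  x <- as_samples(x)
  y <- as_samples(y)
  if (length(x) == 0 || length(y) == 0) {
    stop("dtw inputs must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("dtw inputs must be finite", call. = FALSE)
  }
  dtw_dist_cpp(x, y)
}

#' Mean-pool a series to a fixed length
#'
#' Averages the series over `len` contiguous near-equal bins (balanced,
#' longer bins first), preserving the overall shape at a fraction of the
#' DTW cost.  Series already at or below `len` are returned unchanged.
#'
#' @param x Numeric vector.
#' @param len Target length (>= 2).
#' @return Numeric vector of length `min(len, length(x))`.
#' @export
downsample_series <- function(x, len = 500) {
  x <- as_samples(x)
  if (len < 2) stop("downsample length must be >= 2", call. = FALSE)
  if (length(x) <= len) return(x)
  vapply(segment(x, len), mean, numeric(1))
}

#' DTW class-distance features
#'
#' For each class in the reference collection, the feature is the mean DTW
#' distance from the query waveform to that class's reference members.
#' When the query itself appears among the references (matched by
#' `source_id`), it is excluded from its own class's average and the
#' divisor is the number of remaining members.  Series are mean-pooled to
#' `config$dtw_downsample` points before DTW.  Class order is fixed by
#' sorted label.
#'
#' @param w A [waveform()].
#' @param references A corpus tibble of labelled reference waveforms with
#'   at least one member per class.
#' @param config An [sfx_config()].
#' @return Named numeric vector `dtw_class_<label>`, length = number of
#'   classes.
#' @export
class_dtw_features <- function(w, references, config = sfx_config()) {
  stopifnot(inherits(w, "waveform"))
  check_corpus(references)
  len <- config$dtw_downsample
  q <- downsample_series(w$samples, len)
  classes <- sort(unique(references$label))
  keep <- references$id != w$source_id
  out <- vapply(classes, function(cl) {
    rows <- which(references$label == cl & keep)
    if (length(rows) == 0) {
      stop("class '", cl, "' has no reference members after excluding ",
           "the query itself", call. = FALSE)
    }
    mean(vapply(rows, function(i) {
      dtw(q, downsample_series(references$samples[[i]], len))
    }, numeric(1)))
  }, numeric(1))
  names(out) <- paste0("dtw_class_", classes)
  out
}

# Pairwise DTW distance matrix over pooled series (used by the pipeline to
# avoid recomputing symmetric pairs when extracting a whole corpus).
corpus_dtw_matrix <- function(series_list, len) {
  pooled <- lapply(series_list, downsample_series, len = len)
  n <- length(pooled)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- dtw_dist_cpp(pooled[[i]], pooled[[j]])
      }
    }
  }
  d
}
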