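#' Pipeline configuration
#'
#' Collects every tunable of the feature extractor and selection layer with
#' its documented default.
#'
#' @param n_seg Number of piecewise segments (default 20, the calibrated
#'   optimum for sentence-length recordings).
#' @param n_cc Number of cepstral coefficients in the frequency block
#'   (default 10).
#' @param gamma LPC order compensation (2 or 3, see [lpc_order()]).
#' @param lpc_order Explicit LPC order override (default `NULL`: derived
#'   from the sample rate).
#' @param include_c0 Include `c_0 = ln G` in the frequency block.
#' @param dtw_downsample Mean-pool length before DTW (default 500).
#' @param wavelet_level,wavelet_k Haar baseline depth (3) and retained
#'   coefficient count (50).
#' @param excess_kurtosis Report kurtosis minus 3 instead of the raw form.
#' @param garch_maxiter Optimiser budget per GARCH fit.
#' @param cv_folds Cross-validation folds for wrapper fitness (default 5).
#' @param fs_bins Equal-frequency discretisation bins for the
#'   information-theoretic selectors (default 10).
#' @param mrmr_k Default mRMR subset size (default 30).
#' @param wsa Wolf Search parameters: `n_wolves`, `visual_radius`,
#'   `escape_prob`, `iterations`.
#' @return A list of class `sfx_config`.
#' @export
sfx_config <- function(n_seg = 20, n_cc = 10, gamma = 2, lpc_order = NULL,
                       include_c0 = FALSE, dtw_downsample = 500,
                       wavelet_level = 3, wavelet_k = 50,
                       excess_kurtosis = FALSE, garch_maxiter = 500,
                       cv_folds = 5, fs_bins = 10, mrmr_k = 30,
                       wsa = list(n_wolves = 10, visual_radius = 3,
                                  escape_prob = 0.25, iterations = 50)) {
  structure(
    list(n_seg = as.integer(n_seg), n_cc = as.integer(n_cc), gamma = gamma,
         lpc_order = lpc_order, include_c0 = include_c0,
         dtw_downsample = as.integer(dtw_downsample),
         wavelet_level = as.integer(wavelet_level),
         wavelet_k = as.integer(wavelet_k),
         excess_kurtosis = excess_kurtosis,
         garch_maxiter = as.integer(garch_maxiter),
         cv_folds = as.integer(cv_folds), fs_bins = as.integer(fs_bins),
         mrmr_k = as.integer(mrmr_k), wsa = wsa),
    class = "sfx_config"
  )
}

#' Extract the full SFX feature vector of one waveform
#'
#' Concatenates, in fixed order, the frequency block (cepstral
#' coefficients), the whole-series statistics block, the piecewise block
#' and the DTW class-distance block.  Attribute names are frozen API
#' (`cc_*`, the 12 statistic names, `grad_*`/`rss_*`/`resstd_*`/
#' `volmean_*`/`volstd_*`, `dtw_class_<label>`), so feature-selection
#' masks are portable across runs.  Any non-finite value is replaced by 0
#' and counted in the `n_imputed` attribute.
#'
#' @param w A [waveform()].
#' @param references Corpus tibble of labelled references for the DTW
#'   block.
#' @param config An [sfx_config()].
#' @return One-row tibble of `10 + 12 + 5 * n_seg + C` features plus a
#'   `label` column.
#' @export
extract_sfx <- function(w, references, config = sfx_config()) {
  stopifnot(inherits(w, "waveform"))
  garch <- fit_garch_safe(w$samples, ar_order = 1,
                          maxiter = config$garch_maxiter)
  row <- c(
    cepstral_features(w, config),
    unlist(descriptive_stats(w, garch, config)),
    piecewise_features(w, config),
    class_dtw_features(w, references, config)
  )
  bad <- !is.finite(row)
  row[bad] <- 0
  out <- tibble::as_tibble(as.list(row))
  out$label <- w$label
  attr(out, "n_imputed") <- sum(bad)
  out
}

#' Extract a labelled feature matrix from a corpus
#'
#' Applies one of the three encoders to every waveform of the corpus:
#' `"sfx"` (the full hybrid vector), `"lpc-cc"` (cepstral coefficients
#' only) or `"wavelet"` (top-k Haar coefficients).  For `"sfx"`, DTW
#' references default to the corpus itself with each instance excluded
#' from its own class average (by identity); pass the training corpus as
#' `references` to extract held-out rows without touching their labels.
#'
#' @param corpus Corpus tibble.
#' @param method Encoder name.
#' @param config An [sfx_config()].
#' @param references Optional reference corpus for the DTW block.
#' @return A feature matrix: tibble of numeric features plus a final
#'   `label` column, with attributes `config` and `n_imputed`.
#' @examples
#' corpus <- synth_dataset(synth_preset("fm-like", n_per_class = 2,
#'                                      n_samples = 600))
#' m <- extract_features(corpus, "lpc-cc")
#' dim(m)
#' @export
extract_features <- function(corpus, method = c("sfx", "lpc-cc", "wavelet"),
                             config = sfx_config(), references = NULL) {
  check_corpus(corpus)
  method <- match.arg(method)

  if (method == "lpc-cc") {
    rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
      cepstral_features(corpus_waveform(corpus, i), config)
    })
    return(finish_matrix(rows, corpus$label, config))
  }
  if (method == "wavelet") {
    rows <- purrr::map(corpus$samples, haar_features,
                       level = config$wavelet_level, k = config$wavelet_k)
    return(finish_matrix(rows, corpus$label, config))
  }

  # sfx: share one pooled-DTW distance computation across the corpus
  if (is.null(references)) references <- corpus
  check_corpus(references)
  dtw_block <- corpus_dtw_block(corpus, references, config)
  rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
    w <- corpus_waveform(corpus, i)
    garch <- fit_garch_safe(w$samples, ar_order = 1,
                            maxiter = config$garch_maxiter)
    c(cepstral_features(w, config),
      unlist(descriptive_stats(w, garch, config)),
      piecewise_features(w, config),
      dtw_block[i, ])
  })
  finish_matrix(rows, corpus$label, config)
}

# Mean DTW distance of every corpus row to each reference class, with
# self-exclusion by id; vectorised over a query-by-reference matrix.
corpus_dtw_block <- function(corpus, references, config) {
  len <- config$dtw_downsample
  classes <- sort(unique(references$label))
  qs <- lapply(corpus$samples, downsample_series, len = len)
  rs <- lapply(references$samples, downsample_series, len = len)
  d <- matrix(0, nrow(corpus), nrow(references))
  same <- outer(corpus$id, references$id, `==`)
  for (i in seq_len(nrow(corpus))) {
    for (j in seq_len(nrow(references))) {
      if (!same[i, j]) d[i, j] <- dtw_dist_cpp(qs[[i]], rs[[j]])
    }
  }
  out <- matrix(0, nrow(corpus), length(classes),
                dimnames = list(NULL, paste0("dtw_class_", classes)))
  for (k in seq_along(classes)) {
    cols <- references$label == classes[k]
    for (i in seq_len(nrow(corpus))) {
      use <- cols & !same[i, ]
      if (!any(use)) {
        stop("class '", classes[k], "' has no reference members after ",
             "excluding instance '", corpus$id[i], "'", call. = FALSE)
      }
      out[i, k] <- mean(d[i, use])
    }
  }
  out
}

finish_matrix <- function(rows, labels, config) {
  mat <- do.call(rbind, rows)
  bad <- !is.finite(mat)
  mat[bad] <- 0
  out <- tibble::as_tibble(as.data.frame(mat))
  out$label <- as.character(labels)
  attr(out, "config") <- config
  attr(out, "n_imputed") <- sum(bad)
  out
}

# Split a feature matrix into the numeric design matrix and label vector.
split_matrix <- function(m) {
  if (!"label" %in% names(m)) {
    stop("feature matrix must contain a 'label' column", call. = FALSE)
  }
  list(x = as.matrix(m[setdiff(names(m), "label")]),
       y = as.character(m$label))
}

#' Stratified train/test extraction
#'
#' Splits the corpus by class (stratified, seeded), extracts the training
#' matrix with the training rows as their own DTW references, and extracts
#' the test matrix against the *training* references only, so test
#' features never depend on test labels.
#'
#' @param corpus Corpus tibble with >= 2 classes and >= 2 instances per
#'   class.
#' @param config An [sfx_config()].
#' @param train_frac Training fraction (per class, rounded).
#' @param seed Split seed.
#' @param method Encoder passed to [extract_features()].
#' @return A list with `train` and `test` feature matrices and the row ids
#'   of each side.
#' @export
build_matrix <- function(corpus, config = sfx_config(), train_frac = 0.6,
                         seed = 1L, method = "sfx") {
  check_corpus(corpus)
  counts <- table(corpus$label)
  if (length(counts) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2)) {
    stop("every class needs >= 2 instances for a stratified split",
         call. = FALSE)
  }
  idx <- seq_len(nrow(corpus))
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(names(counts), function(cl) {
      rows <- idx[corpus$label == cl]
      n_tr <- max(1L, min(length(rows) - 1L, round(train_frac * length(rows))))
      sample(rows, n_tr)
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(idx, train_idx)
  train_corpus <- corpus[train_idx, ]
  test_corpus <- corpus[test_idx, ]
  train <- extract_features(train_corpus, method, config)
  test <- if (method == "sfx") {
    extract_features(test_corpus, method, config, references = train_corpus)
  } else {
    extract_features(test_corpus, method, config)
  }
  list(train = train, test = test,
       train_ids = corpus$id[train_idx], test_ids = corpus$id[test_idx])
}

#' Write / read a feature matrix
#'
#' CSV keeps full double precision (round-trips to better than 1e-12);
#' ARFF declares every feature as a numeric attribute and the label as a
#' nominal class, for interoperability with Weka-style tools.
#'
#' @param m Feature matrix (tibble with a `label` column).
#' @param path Output path.
#' @param format `"csv"` or `"arff"`; guessed from the extension when
#'   missing.
#' @return `path` invisibly (`write_matrix`); a feature matrix tibble
#'   (`read_matrix`).
#' @export
write_matrix <- function(m, path, format = NULL) {
  format <- matrix_format(path, format)
  if (!"label" %in% names(m)) {
    stop("feature matrix must contain a 'label' column", call. = FALSE)
  }
  if (format == "csv") {
    readr::write_csv(m, path)
  } else {
    d <- as.data.frame(m)
    d$label <- factor(d$label)
    foreign::write.arff(d, path)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, format = NULL) {
  format <- matrix_format(path, format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    tibble::as_tibble(foreign::read.arff(path))
  }
  if (!"label" %in% names(d)) {
    stop("matrix file is missing the 'label' column", call. = FALSE)
  }
  d$label <- as.character(d$label)
  d
}

matrix_format <- function(path, format) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  if (!format %in% c("csv", "arff")) {
    stop("unknown matrix format: ", format, call. = FALSE)
  }
  format
}
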