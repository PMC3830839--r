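#' Compare preprocessing methods by cross-validated performance
#'
#' The headline experiment of the package: encode the same labelled corpus
#' with each preprocessing method (`wavelet` baseline, `lpc-cc`, full
#' `sfx`, and `sfx-fs` = SFX followed by ensemble feature selection),
#' score each encoding by stratified k-fold cross-validation with the same
#' classifier and folds, and report the full metric suite per method.
#'
#' @param corpus Corpus tibble.
#' @param methods Preprocessing methods to compare.
#' @param classifier An [sfx_classifier()].
#' @param config An [sfx_config()].
#' @param seed Seed controlling CV folds and the feature-selection search.
#' @param fs_methods Selector names forwarded to [ensemble_select()].
#' @return A tibble with one row per method: accuracy, kappa,
#'   macro/weighted precision, recall, F, macro ROC AUC, and the number of
#'   attributes used (after selection, for `sfx-fs`).
#' @export
compare_preprocessing <- function(corpus,
                                  methods = c("wavelet", "lpc-cc", "sfx",
                                              "sfx-fs"),
                                  classifier = sfx_classifier("tree"),
                                  config = sfx_config(), seed = 1L,
                                  fs_methods = c("chi2", "cfs", "mrmr",
                                                 "wsa")) {
  check_corpus(corpus)
  sfx_matrix <- NULL
  get_sfx <- function() {
    if (is.null(sfx_matrix)) {
      sfx_matrix <<- extract_features(corpus, "sfx", config)
    }
    sfx_matrix
  }
  rows <- purrr::map(methods, function(meth) {
    if (meth == "sfx-fs") {
      m <- get_sfx()
      sel <- ensemble_select(m, methods = fs_methods,
                             classifier = classifier, config = config,
                             seed = seed)
      m <- mask_matrix(m, sel)
      extra <- list(n_attributes = sum(sel$mask), fs_method = sel$method)
    } else if (meth == "sfx") {
      m <- get_sfx()
      extra <- list(n_attributes = ncol(m) - 1L, fs_method = NA_character_)
    } else {
      m <- extract_features(corpus, meth, config)
      extra <- list(n_attributes = ncol(m) - 1L, fs_method = NA_character_)
    }
    cv <- cross_validate(m, classifier, folds = config$cv_folds,
                         seed = seed)
    lev <- sort(unique(m$label))
    rep <- metrics_report(cv$predictions$predicted, cv$predictions$actual,
                          scores = as.matrix(cv$predictions[lev]))
    dplyr::bind_cols(tibble::tibble(method = meth), glance(rep),
                     tibble::as_tibble(extra))
  })
  dplyr::bind_rows(rows)
}
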