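Package: sfx
Title: Statistical Feature Extraction and Ensemble Feature Selection for
    Voice Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns raw one-dimensional acoustic or physiological waveforms
    into classification-ready feature matrices using a hybrid
    frequency-domain and time-domain extractor (SFX): linear prediction
    coding mapped to cepstral coefficients, whole-series descriptive
    statistics with AR(1)+GARCH(1,1) residual and volatility summaries,
    dynamic-time-warping class-distance features, and piecewise linear
    segment statistics.  Includes an ensemble feature-selection layer
    (chi-square ranking, correlation-based feature selection, minimum
    redundancy maximum relevance, and a binary Wolf Search wrapper),
    reference classifiers behind a pluggable contract, a full evaluation
    suite (Cohen's kappa, precision/recall/F, ROC AUC), a labelled
    synthetic voice-like waveform generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
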