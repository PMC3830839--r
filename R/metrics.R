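#' Confusion matrix (rows = predicted, columns = actual)
#'
#' @param predicted,actual Label vectors of equal length.
#' @param levels Class order; defaults to the sorted union of labels.
#' @return A `confusion_matrix` (integer matrix with class attributes).
#' @export
confusion_matrix <- function(predicted, actual, levels = NULL) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (is.null(levels)) levels <- sort(unique(c(predicted, actual)))
  cm <- table(factor(predicted, levels), factor(actual, levels))
  out <- matrix(as.integer(cm), nrow(cm), ncol(cm),
                dimnames = list(predicted = levels, actual = levels))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Cohen's kappa statistic
#'
#' Chance-corrected agreement `(Pr(a) - Pr(e)) / (1 - Pr(e))` where
#' `Pr(a)` is the observed agreement (trace / total) and `Pr(e)` the
#' expected chance agreement from the margins.  When `Pr(e) = 1` the
#' statistic is undefined; the convention here returns 1 if agreement is
#' perfect and 0 otherwise.
#'
#' @param cm A [confusion_matrix()] (or plain square count matrix).
#' @return Scalar kappa in `[-1, 1]`.
#' @examples
#' kappa_statistic(matrix(c(20, 10, 5, 15), 2))  # 0.4
#' @export
kappa_statistic <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  pr_a <- sum(diag(cm)) / total
  pr_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pr_e) < .Machine$double.eps) {
    return(if (pr_a >= 1 - .Machine$double.eps) 1 else 0)
  }
  (pr_a - pr_e) / (1 - pr_e)
}

#' Per-class precision, recall and F score
#'
#' One-vs-rest decomposition of the confusion matrix (rows = predicted):
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and the
#' F-beta score `(1 + b^2) * P * R / (b^2 * P + R)` (harmonic mean at
#' `beta = 1`).  A zero denominator yields 0 with a warning.  Macro
#' averages are unweighted means; weighted averages use class support.
#'
#' @param cm A [confusion_matrix()].
#' @param beta F score weight (default 1).
#' @return Tibble with one row per class plus attributes `macro` and
#'   `weighted` (named vectors precision/recall/f).
#' @export
precision_recall_f <- function(cm, beta = 1) {
  cm_u <- unclass(cm)
  classes <- rownames(cm_u)
  tp <- diag(cm_u)
  fp <- rowSums(cm_u) - tp   # predicted as class but actually other
  fn <- colSums(cm_u) - tp   # actually class but predicted other
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning("zero denominator in ", what, "; reporting 0", call. = FALSE)
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f <- ifelse(beta^2 * precision + recall > 0,
              (1 + beta^2) * precision * recall /
                (beta^2 * precision + recall), 0)
  support <- colSums(cm_u)
  out <- tibble::tibble(class = classes, precision = unname(precision),
                        recall = unname(recall), f = unname(f),
                        support = unname(support))
  wt <- support / sum(support)
  attr(out, "macro") <- c(precision = mean(precision), recall = mean(recall),
                          f = mean(f))
  attr(out, "weighted") <- c(precision = sum(wt * precision),
                             recall = sum(wt * recall), f = sum(wt * f))
  out
}

#' One-vs-rest ROC AUC
#'
#' For each class, the area under the empirical ROC curve of that class's
#' score column against the binary (class vs rest) truth, computed by the
#' rank (Mann-Whitney) formulation with midrank tie handling - identical
#' to the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric matrix (instances x classes) with class names as
#'   columns, or a vector for the binary case.
#' @param labels True labels.
#' @return A list: `per_class` tibble and `macro` (mean AUC over classes
#'   evaluable with at least one positive and one negative).
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    stop("labels contain a single class; AUC is undefined", call. = FALSE)
  }
  if (is.vector(scores)) {
    lev <- sort(unique(labels))
    if (length(lev) != 2) {
      stop("vector scores require exactly two classes", call. = FALSE)
    }
    scores <- cbind(1 - scores, scores)
    colnames(scores) <- lev
  }
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  classes <- colnames(scores)
  auc <- vapply(classes, function(cl) {
    pos <- labels == cl
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) return(NA_real_)
    r <- rank(scores[, cl], ties.method = "average")
    (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }, numeric(1))
  list(per_class = tibble::tibble(class = classes, auc = unname(auc)),
       macro = mean(auc, na.rm = TRUE))
}

#' Full evaluation report
#'
#' Bundles the confusion matrix with accuracy, Cohen's kappa, per-class
#' and macro/weighted precision-recall-F, and (when scores are supplied)
#' one-vs-rest ROC AUC.
#'
#' @param predicted,actual Label vectors.
#' @param scores Optional per-class score matrix for ROC analysis.
#' @param beta F score weight.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(predicted, actual, scores = NULL, beta = 1) {
  cm <- confusion_matrix(predicted, actual)
  prf <- precision_recall_f(cm, beta = beta)
  auc <- if (!is.null(scores)) roc_auc(scores, actual) else NULL
  structure(
    list(confusion = cm,
         accuracy = sum(diag(unclass(cm))) / sum(cm),
         kappa = kappa_statistic(cm),
         per_class = prf,
         macro = attr(prf, "macro"),
         weighted = attr(prf, "weighted"),
         auc = auc),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f, kappa %.4f", x$accuracy,
              x$kappa))
  if (!is.null(x$auc)) cat(sprintf(", macro AUC %.4f", x$auc$macro))
  cat("\n")
  print(x$per_class)
  invisible(x)
}

#' @rdname metrics_report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) {
  out <- x$per_class
  if (!is.null(x$auc)) {
    out <- dplyr::left_join(out, x$auc$per_class, by = "class")
  }
  out
}

#' @rdname metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, kappa = x$kappa,
    precision_macro = unname(x$macro["precision"]),
    recall_macro = unname(x$macro["recall"]),
    f_macro = unname(x$macro["f"]),
    precision_weighted = unname(x$weighted["precision"]),
    recall_weighted = unname(x$weighted["recall"]),
    f_weighted = unname(x$weighted["f"]),
    auc_macro = if (is.null(x$auc)) NA_real_ else x$auc$macro
  )
}

#' @rdname metrics_report
#' @param object A `metrics_report`.
#' @export
autoplot.metrics_report <- function(object, ...) {
  d <- as.data.frame(as.table(unclass(object$confusion)))
  names(d) <- c("predicted", "actual", "count")
  ggplot2::ggplot(d, ggplot2::aes(.data$actual, .data$predicted,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("accuracy %.3f, kappa %.3f",
                                  object$accuracy, object$kappa)) +
    ggplot2::theme_minimal()
}
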