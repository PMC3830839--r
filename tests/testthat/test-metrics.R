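test_that("kappa matches hand evaluations and conventions", {
  # perfect diagonal
  expect_identical(kappa_statistic(diag(5)), 1)
  # [[20,5],[10,15]]: Pr(a) = 0.7, Pr(e) = 0.5 -> kappa = 0.4
  cm <- matrix(c(20, 10, 5, 15), 2)
  expect_equal(kappa_statistic(cm), 0.4, tolerance = 1e-12)
  # Pr(a) = Pr(e) -> 0 (independence margins)
  cm0 <- matrix(c(25, 25, 25, 25), 2)
  expect_equal(kappa_statistic(cm0), 0)
  expect_error(kappa_statistic(matrix(0, 2, 2)), "empty")
})

test_that("precision/recall/F decompose the confusion matrix correctly", {
  # one-vs-rest hand case: TP = 8, FP = 2 -> precision 0.8
  cm <- confusion_matrix(c(rep("a", 10), rep("b", 10)),
                         c(rep("a", 8), rep("b", 2), rep("b", 10)))
  prf <- precision_recall_f(cm)
  expect_equal(prf$precision[prf$class == "a"], 0.8)
  expect_equal(prf$recall[prf$class == "a"], 1)
  expect_equal(prf$precision[prf$class == "b"], 1)
  expect_equal(prf$recall[prf$class == "b"], 10 / 12)

  # orientation: rows are predictions
  expect_identical(unname(unclass(cm)["a", "b"]), 2L)
})

test_that("F-beta at beta = 1 reproduces the harmonic mean on random tables", {
  set.seed(33)
  for (k in 1:50) {
    cm <- matrix(rpois(9, 10) + 1, 3,
                 dimnames = list(predicted = letters[1:3],
                                 actual = letters[1:3]))
    class(cm) <- c("confusion_matrix", class(cm))
    p1 <- precision_recall_f(cm, beta = 1)
    f_hand <- 2 * p1$precision * p1$recall / (p1$precision + p1$recall)
    expect_equal(p1$f, f_hand, tolerance = 1e-12)
  }
})

test_that("micro-averaged one-vs-rest precision and recall equal accuracy", {
  set.seed(34)
  pred <- sample(letters[1:3], 200, replace = TRUE)
  act <- ifelse(runif(200) < 0.6, pred, sample(letters[1:3], 200,
                                               replace = TRUE))
  cm <- confusion_matrix(pred, act)
  tp <- sum(diag(unclass(cm)))
  fp <- sum(rowSums(unclass(cm)) - diag(unclass(cm)))
  fn <- sum(colSums(unclass(cm)) - diag(unclass(cm)))
  acc <- tp / sum(cm)
  expect_equal(tp / (tp + fp), acc, tolerance = 1e-12)
  expect_equal(tp / (tp + fn), acc, tolerance = 1e-12)
})

test_that("metrics are invariant to class-order permutation", {
  pred <- c("a", "a", "b", "c", "c", "b", "a")
  act <- c("a", "b", "b", "c", "a", "b", "a")
  r1 <- metrics_report(pred, act)
  r2 <- metrics_report(pred, act)
  expect_equal(r1$accuracy, r2$accuracy)
  cm_perm <- confusion_matrix(pred, act, levels = c("c", "a", "b"))
  expect_equal(kappa_statistic(cm_perm), r1$kappa, tolerance = 1e-12)
  prf <- precision_recall_f(cm_perm)
  expect_equal(prf$precision[order(prf$class)],
               r1$per_class$precision[order(r1$per_class$class)])
})

test_that("rank AUC equals the trapezoidal ROC area and handles extremes", {
  # perfect ranking
  auc <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c("n", "n", "p", "p"))
  expect_identical(auc$per_class$auc[auc$per_class$class == "p"], 1)

  set.seed(35)
  for (k in 1:100) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), 2)  # ties on purpose
    labs <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    r <- roc_auc(cbind(p = scores, n = 1 - scores), labs)
    expect_equal(r$per_class$auc[r$per_class$class == "p"],
                 bf_trapezoid_auc(scores, labs == "p"), tolerance = 1e-9)
  }
  expect_error(roc_auc(runif(5), rep("p", 5)), "single class")
})

test_that("labels independent of scores give AUC near one half", {
  set.seed(36)
  scores <- runif(2000)
  labs <- sample(c("p", "n"), 2000, replace = TRUE)
  r <- roc_auc(cbind(p = scores, n = 1 - scores), labs)
  expect_lt(abs(r$macro - 0.5), 0.05)
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  scores <- rnorm(100)
  labs <- ifelse(scores + rnorm(100) > 0, "p", "n")
  ours <- roc_auc(cbind(p = scores, n = -scores), labs)
  ref <- as.numeric(pROC::auc(pROC::roc(labs, scores, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours$per_class$auc[ours$per_class$class == "p"], ref,
               tolerance = 1e-9)
})

test_that("the aggregated report is consistent and tidy-able", {
  set.seed(38)
  m <- make_shifted_matrix(n_per_class = 20, informative = 2, noise = 2,
                           shift = 2)
  cv <- cross_validate(m, sfx_classifier("lda"), folds = 5, seed = 2)
  rep <- metrics_report(cv$predictions$predicted, cv$predictions$actual,
                        scores = as.matrix(cv$predictions[c("a", "b")]))
  expect_equal(rep$accuracy, cv$accuracy)
  expect_equal(rep$accuracy,
               sum(diag(unclass(rep$confusion))) / sum(rep$confusion))
  expect_lte(rep$kappa, 1)
  gl <- glance(rep)
  expect_identical(ncol(gl), 9L)
  td <- tidy(rep)
  expect_true(all(c("precision", "recall", "f", "auc") %in% names(td)))
})
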