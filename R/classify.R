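#' Reference classifiers behind a uniform contract
#'
#' Three built-ins cover the plug-and-play classifier contract used by the
#' wrapper feature selection and the evaluation layer:
#' \describe{
#'   \item{`tree`}{an information-gain decision tree (rpart with the
#'     information split criterion).}
#'   \item{`centroid`}{nearest class centroid in Euclidean distance.}
#'   \item{`lda`}{a regularized linear discriminant with a ridge term on
#'     the pooled covariance, so collinear feature blocks do not break
#'     the fit.}
#' }
#' Any object implementing `fit(classifier, m)` and
#' `predict(fitted, m, type = "class"|"score")` can be substituted.
#'
#' @param type Built-in classifier name.
#' @param seed Seed applied around fitting (kept for reproducibility of
#'   any stochastic classifier honoring the contract; the built-ins are
#'   deterministic).
#' @param lambda Ridge weight for `lda` (fraction of the mean covariance
#'   diagonal).
#' @return An object of class `sfx_classifier`.
#' @examples
#' m <- tibble::tibble(x1 = c(0, 0, 10, 10), x2 = c(0, 1, 10, 11),
#'                     label = c("a", "a", "b", "b"))
#' f <- fit(sfx_classifier("centroid"), m)
#' predict(f, m)
#' @export
sfx_classifier <- function(type = c("tree", "centroid", "lda"), seed = 1L,
                           lambda = 1e-3) {
  type <- match.arg(type)
  structure(list(type = type, seed = as.integer(seed), lambda = lambda),
            class = "sfx_classifier")
}

#' @rdname sfx_classifier
#' @param object An `sfx_classifier`.
#' @param m Feature matrix tibble with a `label` column.
#' @param ... Unused.
#' @export
fit.sfx_classifier <- function(object, m, ...) {
  parts <- split_matrix(m)
  x <- parts$x
  y <- factor(parts$y)
  model <- withr::with_seed(object$seed, switch(
    object$type,
    tree = {
      d <- as.data.frame(x)
      d$.label <- y
      # minsplit relaxed so trees remain usable on corpus-scale folds
      rpart::rpart(.label ~ ., data = d, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(xval = 0, cp = 0.01,
                                                  minsplit = 5,
                                                  minbucket = 2))
    },
    centroid = {
      mu <- rowsum(x, y) / as.vector(table(y))
      list(centroids = mu)
    },
    lda = fit_rlda(x, y, object$lambda)
  ))
  structure(list(spec = object, model = model, levels = levels(y),
                 features = colnames(x)),
            class = "sfx_fitted")
}

fit_rlda <- function(x, y, lambda) {
  lev <- levels(y)
  mu <- rowsum(x, y) / as.vector(table(y))
  centered <- x - mu[as.integer(y), , drop = FALSE]
  s <- crossprod(centered) / max(1, nrow(x) - length(lev))
  ridge <- lambda * mean(diag(s)) + 1e-12
  s_reg <- s + diag(ridge, ncol(x))
  w <- solve(s_reg, t(mu))                       # p x C
  b <- -0.5 * colSums(t(mu) * w) + log(as.vector(table(y)) / nrow(x))
  list(w = w, b = b)
}

#' @export
predict.sfx_fitted <- function(object, m, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.data.frame(m)) {
    x <- as.matrix(m[intersect(object$features, names(m))])
  } else {
    x <- as.matrix(m)[, object$features, drop = FALSE]
  }
  if (!identical(colnames(x), object$features)) {
    stop("prediction features do not match the fitted features",
         call. = FALSE)
  }
  scores <- switch(
    object$spec$type,
    tree = {
      pr <- stats::predict(object$model, as.data.frame(x), type = "prob")
      pr[, object$levels, drop = FALSE]
    },
    centroid = {
      cen <- object$model$centroids
      d2 <- outer(rowSums(x^2), rep(1, nrow(cen))) -
        2 * x %*% t(cen) + outer(rep(1, nrow(x)), rowSums(cen^2))
      score_from_distance(-d2, rownames(cen), object$levels)
    },
    lda = {
      g <- x %*% object$model$w +
        matrix(object$model$b, nrow(x), length(object$levels), byrow = TRUE)
      colnames(g) <- colnames(object$model$w)
      score_from_distance(g, colnames(g), object$levels)
    }
  )
  if (type == "score") return(scores)
  object$levels[max.col(scores, ties.method = "first")]
}

# Min-max normalise per instance so non-probabilistic discriminants yield
# comparable [0, 1] scores for ROC analysis.
score_from_distance <- function(g, cols, levels) {
  g <- g[, levels, drop = FALSE]
  rng <- apply(g, 1, function(r) diff(range(r)))
  lo <- apply(g, 1, min)
  s <- (g - lo) / ifelse(rng > 0, rng, 1)
  s[rng == 0, ] <- 1 / ncol(g)
  rownames(s) <- NULL
  s
}

#' Stratified cross-validation
#'
#' Splits instances into `folds` stratified folds (seeded) and evaluates
#' the classifier out of fold; no instance is ever predicted by a model
#' trained on it.
#'
#' @param m Feature matrix tibble with a `label` column.
#' @param classifier An [sfx_classifier()] (or compatible object).
#' @param folds Number of folds (>= 2; every class must have at least
#'   `folds` members).
#' @param seed Fold assignment seed.
#' @param fold_id Optional precomputed fold assignment (integer vector),
#'   used to evaluate several masks on identical folds.
#' @return A list: `accuracy` (mean out-of-fold accuracy), `predictions`
#'   (tibble with row, fold, actual, predicted and per-class scores),
#'   `fold_id`, `fold_accuracy`.
#' @export
cross_validate <- function(m, classifier = sfx_classifier("tree"),
                           folds = 5, seed = 1L, fold_id = NULL) {
  parts <- split_matrix(m)
  y <- parts$y
  if (is.null(fold_id)) fold_id <- make_folds(y, folds, seed)
  folds <- max(fold_id)
  lev <- sort(unique(y))
  preds <- character(length(y))
  scores <- matrix(NA_real_, length(y), length(lev),
                   dimnames = list(NULL, lev))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fitted <- fit(classifier, m[!hold, , drop = FALSE])
    preds[hold] <- predict(fitted, m[hold, , drop = FALSE])
    sc <- predict(fitted, m[hold, , drop = FALSE], type = "score")
    scores[hold, colnames(sc)] <- sc
  }
  fold_acc <- vapply(seq_len(folds), function(f) {
    mean(preds[fold_id == f] == y[fold_id == f])
  }, numeric(1))
  list(
    accuracy = mean(preds == y),
    predictions = dplyr::bind_cols(
      tibble::tibble(row = seq_along(y), fold = fold_id, actual = y,
                     predicted = preds),
      tibble::as_tibble(as.data.frame(scores))
    ),
    fold_id = fold_id,
    fold_accuracy = fold_acc
  )
}

#' @rdname cross_validate
#' @param y Label vector (for `make_folds`).
#' @export
make_folds <- function(y, folds = 5, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  counts <- table(y)
  if (any(counts < folds)) {
    stop("every class needs at least ", folds, " instances for ", folds,
         "-fold stratified CV", call. = FALSE)
  }
  fold_id <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in names(counts)) {
      rows <- which(y == cl)
      fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
  })
  fold_id
}
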