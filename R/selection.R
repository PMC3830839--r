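#' Equal-frequency discretisation
#'
#' Cuts a numeric feature at its empirical quantiles into at most `bins`
#' intervals.  Robust to heavy-tailed features; a constant feature
#' collapses to a single bin.
#'
#' @param x Numeric vector.
#' @param bins Number of bins (>= 2).
#' @return Integer bin codes in `1..bins`.
#' @export
discretize_ef <- function(x, bins = 10) {
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        type = 7, names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE, labels = FALSE))
}

# Plug-in entropy / mutual information on discrete codes (nats).
entropy_disc <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

mutual_info_disc <- function(x, y) {
  entropy_disc(x) + entropy_disc(y) - entropy_disc(paste(x, y))
}

# Symmetrical uncertainty in [0, 1].
symmetrical_uncertainty <- function(x, y) {
  hx <- entropy_disc(x)
  hy <- entropy_disc(y)
  if (hx + hy == 0) return(0)
  2 * mutual_info_disc(x, y) / (hx + hy)
}

discretize_matrix <- function(m, bins) {
  parts <- split_matrix(m)
  list(x = apply(parts$x, 2, discretize_ef, bins = bins), y = parts$y)
}

#' Chi-square relevance scores
#'
#' Discretises each feature (equal-frequency) and computes the chi-square
#' statistic of the feature-bin by class contingency table,
#' `sum((N - E)^2 / E)` over all cells, generalising the textbook 2x2
#' term/class form to multiple bins and classes.  Higher means more
#' class-relevant; a constant feature scores 0.
#'
#' @param m Feature matrix tibble with a `label` column.
#' @param bins Discretisation bins.
#' @return Tibble with `feature` and `score`, in matrix column order.
#' @export
chi_square_scores <- function(m, bins = 10) {
  d <- discretize_matrix(m, bins)
  scores <- apply(d$x, 2, function(col) chi_square_stat(col, d$y))
  tibble::tibble(feature = colnames(d$x), score = unname(scores))
}

chi_square_stat <- function(x, y) {
  tab <- table(x, y)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

#' Chi-square filter selection
#'
#' Ranks features by [chi_square_scores()] and picks the retained count
#' `k` by cross-validated accuracy over a small grid (default
#' `{10, 20, 30, u/2}`, clipped to the matrix width).
#'
#' @param m Feature matrix tibble.
#' @param classifier Fitness classifier.
#' @param config An [sfx_config()] (bins, folds).
#' @param seed CV fold seed.
#' @param k_grid Candidate subset sizes.
#' @return A `selection_result`.
#' @export
chi_square_select <- function(m, classifier = sfx_classifier("tree"),
                              config = sfx_config(), seed = 1L,
                              k_grid = NULL) {
  u <- ncol(m) - 1L
  ranked <- dplyr::arrange(chi_square_scores(m, config$fs_bins),
                           dplyr::desc(.data$score))
  if (is.null(k_grid)) k_grid <- c(10, 20, 30, floor(u / 2))
  k_grid <- sort(unique(pmin(pmax(k_grid, 1L), u)))
  fold_id <- make_folds(m$label, config$cv_folds, seed)
  evals <- 0L
  best <- NULL
  for (k in k_grid) {
    mask <- names(m)[-match("label", names(m))] %in% ranked$feature[1:k]
    acc <- cross_validate(mask_matrix(m, mask), classifier,
                          fold_id = fold_id)$accuracy
    evals <- evals + 1L
    if (is.null(best) || acc > best$fitness) {
      best <- list(mask = mask, fitness = acc)
    }
  }
  selection_result("chi2", best$mask, m, best$fitness, evals, seed)
}

#' Correlation-based feature selection (CFS)
#'
#' Greedy forward search maximising the merit
#' `k * rcf / sqrt(k + k (k - 1) * rff)`, where `rcf` is the mean
#' feature-class correlation and `rff` the mean feature-feature
#' correlation of the current subset, both measured as symmetrical
#' uncertainty on equal-frequency-discretised data.  The search stops when
#' no addition improves the merit.
#'
#' @inheritParams chi_square_select
#' @return A `selection_result` (fitness re-scored by CV on the selected
#'   mask).
#' @export
cfs_select <- function(m, classifier = sfx_classifier("tree"),
                       config = sfx_config(), seed = 1L) {
  u <- ncol(m) - 1L
  if (u < 2) stop("CFS needs at least 2 features", call. = FALSE)
  d <- discretize_matrix(m, config$fs_bins)
  rcf <- vapply(seq_len(u), function(j) {
    symmetrical_uncertainty(d$x[, j], d$y)
  }, numeric(1))
  rff <- matrix(NA_real_, u, u)          # lazy pairwise SU cache
  get_rff <- function(i, j) {
    if (is.na(rff[i, j])) {
      v <- symmetrical_uncertainty(d$x[, i], d$x[, j])
      rff[i, j] <<- v
      rff[j, i] <<- v
    }
    rff[i, j]
  }
  selected <- integer(0)
  best_merit <- -Inf
  repeat {
    cand <- setdiff(seq_len(u), selected)
    if (length(cand) == 0) break
    merits <- vapply(cand, function(j) {
      s <- c(selected, j)
      k <- length(s)
      mean_rcf <- mean(rcf[s])
      mean_rff <- if (k == 1) 0 else {
        pairs <- utils::combn(s, 2)
        mean(vapply(seq_len(ncol(pairs)), function(p) {
          get_rff(pairs[1, p], pairs[2, p])
        }, numeric(1)))
      }
      cfs_merit(k, mean_rcf, mean_rff)
    }, numeric(1))
    if (max(merits) <= best_merit + 1e-12) break
    pick <- cand[which.max(merits)]
    selected <- c(selected, pick)
    best_merit <- max(merits)
  }
  mask <- seq_len(u) %in% selected
  fold_id <- make_folds(m$label, config$cv_folds, seed)
  fitness <- cross_validate(mask_matrix(m, mask), classifier,
                            fold_id = fold_id)$accuracy
  res <- selection_result("cfs", mask, m, fitness, length(selected), seed)
  res$merit <- best_merit
  res
}

#' @rdname cfs_select
#' @param k Subset size.
#' @param mean_rcf,mean_rff Mean feature-class and feature-feature
#'   correlations.
#' @export
cfs_merit <- function(k, mean_rcf, mean_rff) {
  k * mean_rcf / sqrt(k + k * (k - 1) * mean_rff)
}

#' Minimum redundancy maximum relevance (mRMR) selection
#'
#' Incremental greedy selection on discretised mutual information: the
#' first pick maximises `I(x; c)`; each later pick maximises
#' `I(x; c) - mean_{s in S} I(x; s)` over the remaining candidates.
#'
#' @inheritParams chi_square_select
#' @param target_k Number of features to select (default from config).
#' @return A `selection_result`.
#' @export
mrmr_select <- function(m, target_k = NULL,
                        classifier = sfx_classifier("tree"),
                        config = sfx_config(), seed = 1L) {
  u <- ncol(m) - 1L
  if (is.null(target_k)) target_k <- config$mrmr_k
  if (target_k < 1) stop("target_k must be >= 1", call. = FALSE)
  target_k <- min(target_k, u)
  d <- discretize_matrix(m, config$fs_bins)
  rel <- vapply(seq_len(u), function(j) {
    mutual_info_disc(d$x[, j], d$y)
  }, numeric(1))
  red <- matrix(NA_real_, u, u)
  get_red <- function(i, j) {
    if (is.na(red[i, j])) {
      v <- mutual_info_disc(d$x[, i], d$x[, j])
      red[i, j] <<- v
      red[j, i] <<- v
    }
    red[i, j]
  }
  selected <- which.max(rel)
  while (length(selected) < target_k) {
    cand <- setdiff(seq_len(u), selected)
    crit <- vapply(cand, function(j) {
      rel[j] - mean(vapply(selected, function(s) get_red(j, s), numeric(1)))
    }, numeric(1))
    selected <- c(selected, cand[which.max(crit)])
  }
  mask <- seq_len(u) %in% selected
  fold_id <- make_folds(m$label, config$cv_folds, seed)
  fitness <- cross_validate(mask_matrix(m, mask), classifier,
                            fold_id = fold_id)$accuracy
  res <- selection_result("mrmr", mask, m, fitness, target_k, seed)
  res$order <- selected
  res
}

#' Wolf Search wrapper feature selection
#'
#' Binary-encoded metaheuristic wrapper.  Each wolf is a feature mask
#' whose fitness is the stratified k-fold CV accuracy of the wrapped
#' classifier on the masked matrix (folds fixed per run, fitness values
#' cached).  Per iteration each wolf: (a) evaluates a random neighbour
#' within Hamming distance `visual_radius` and moves if fitter; (b) moves
#' toward the best fitter companion within visual range by adopting each
#' differing bit with probability 1/2; (c) escapes with probability
#' `escape_prob` by flipping a random larger set of bits.  The best mask
#' ever evaluated is returned (elitist), so best-so-far fitness is
#' non-decreasing.  Fully reproducible given the seed.
#'
#' @inheritParams chi_square_select
#' @param n_wolves,visual_radius,escape_prob,iterations Search parameters
#'   (defaults from `config$wsa`).
#' @return A `selection_result` with an `evaluations` count (distinct
#'   masks evaluated) and a `trace` of best-so-far fitness.
#' @export
wsa_select <- function(m, classifier = sfx_classifier("tree"),
                       config = sfx_config(), seed = 1L,
                       n_wolves = NULL, visual_radius = NULL,
                       escape_prob = NULL, iterations = NULL) {
  u <- ncol(m) - 1L
  p <- config$wsa
  if (is.null(n_wolves)) n_wolves <- p$n_wolves
  if (is.null(visual_radius)) visual_radius <- p$visual_radius
  if (is.null(escape_prob)) escape_prob <- p$escape_prob
  if (is.null(iterations)) iterations <- p$iterations
  stopifnot(n_wolves >= 1, visual_radius >= 1, iterations >= 1,
            escape_prob >= 0, escape_prob <= 1)

  fold_id <- make_folds(m$label, config$cv_folds, seed)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fitness_of <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (is.null(cache[[key]])) {
      evals <<- evals + 1L
      cache[[key]] <- cross_validate(mask_matrix(m, mask), classifier,
                                     fold_id = fold_id)$accuracy
    }
    cache[[key]]
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(u, 1)] <- TRUE
    mask
  }
  flip <- function(mask, k) {
    idx <- sample.int(u, min(k, u))
    mask[idx] <- !mask[idx]
    repair(mask)
  }

  withr::with_seed(as.integer(seed), {
    wolves <- lapply(seq_len(n_wolves), function(i) {
      repair(runif(u) < 0.5)
    })
    fits <- vapply(wolves, fitness_of, numeric(1))
    best_mask <- wolves[[which.max(fits)]]
    best_fit <- max(fits)
    trace <- numeric(iterations)

    for (it in seq_len(iterations)) {
      for (i in seq_len(n_wolves)) {
        # (a) prey search: one random neighbour at each Hamming distance
        # up to the visual radius; move to the best if it is fitter
        for (d in seq_len(visual_radius)) {
          nb <- flip(wolves[[i]], d)
          if (fitness_of(nb) > fits[i]) {
            wolves[[i]] <- nb
            fits[i] <- fitness_of(nb)
          }
        }
        # (b) join a better companion within visual range
        ham <- vapply(wolves, function(wm) sum(wm != wolves[[i]]),
                      numeric(1))
        comp <- which(ham > 0 & ham <= visual_radius & fits > fits[i])
        if (length(comp) > 0) {
          towards <- comp[which.max(fits[comp])]
          diff_bits <- which(wolves[[i]] != wolves[[towards]])
          take <- diff_bits[runif(length(diff_bits)) < 0.5]
          cand <- wolves[[i]]
          cand[take] <- wolves[[towards]][take]
          cand <- repair(cand)
          if (fitness_of(cand) > fits[i]) {
            wolves[[i]] <- cand
            fits[i] <- fitness_of(cand)
          }
        }
        # (c) escape: a larger random jump out of a local trap
        if (runif(1) < escape_prob) {
          jump <- visual_radius +
            sample.int(max(1L, min(u, 3L * visual_radius) - visual_radius), 1)
          wolves[[i]] <- flip(wolves[[i]], jump)
          fits[i] <- fitness_of(wolves[[i]])
        }
        if (fits[i] > best_fit) {
          best_fit <- fits[i]
          best_mask <- wolves[[i]]
        }
      }
      trace[it] <- best_fit
      if (best_fit >= 1) {           # accuracy is capped; nothing to gain
        trace[it:iterations] <- best_fit
        break
      }
    }
    res <- selection_result("wsa", best_mask, m, best_fit, evals, seed)
    res$trace <- trace
    res
  })
}

#' Winner-take-all ensemble feature selection
#'
#' Runs the requested selectors, re-scores every returned mask with the
#' same CV folds and classifier, and returns the highest-fitness result.
#' Ties are broken by fewer selected features, then by method order.
#'
#' @inheritParams chi_square_select
#' @param methods Selector names among `"chi2", "cfs", "mrmr", "wsa"`.
#' @return The winning `selection_result`, with the per-method re-scored
#'   comparison attached as `$comparison`.
#' @export
ensemble_select <- function(m, methods = c("chi2", "cfs", "mrmr", "wsa"),
                            classifier = sfx_classifier("tree"),
                            config = sfx_config(), seed = 1L) {
  stopifnot(length(methods) >= 1)
  runners <- list(
    chi2 = function() chi_square_select(m, classifier, config, seed),
    cfs  = function() cfs_select(m, classifier, config, seed),
    mrmr = function() mrmr_select(m, NULL, classifier, config, seed),
    wsa  = function() wsa_select(m, classifier, config, seed)
  )
  bad <- setdiff(methods, names(runners))
  if (length(bad) > 0) stop("unknown methods: ", paste(bad, collapse = ", "),
                            call. = FALSE)
  results <- list()
  errors <- character(0)
  for (meth in methods) {
    r <- tryCatch(runners[[meth]](), error = function(e) e)
    if (inherits(r, "error")) {
      errors <- c(errors, paste0(meth, ": ", conditionMessage(r)))
    } else {
      results[[meth]] <- r
    }
  }
  if (length(results) == 0) {
    stop("all selection methods failed:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  fold_id <- make_folds(m$label, config$cv_folds, seed)
  rescored <- vapply(results, function(r) {
    cross_validate(mask_matrix(m, r$mask), classifier,
                   fold_id = fold_id)$accuracy
  }, numeric(1))
  sizes <- vapply(results, function(r) sum(r$mask), numeric(1))
  ord <- order(-rescored, sizes, match(names(results), methods))
  winner <- results[[ord[1]]]
  winner$fitness <- rescored[[ord[1]]]
  winner$comparison <- tibble::tibble(
    method = names(results), fitness = unname(rescored),
    n_selected = unname(sizes)
  )
  if (length(errors) > 0) winner$failed <- errors
  winner
}

# ---- selection result container ------------------------------------------

selection_result <- function(method, mask, m, fitness, evaluations, seed) {
  feats <- setdiff(names(m), "label")
  mask <- as.logical(mask)
  stopifnot(length(mask) == length(feats))
  if (!any(mask)) stop("selection produced an empty mask", call. = FALSE)
  structure(
    list(method = method, mask = stats::setNames(mask, feats),
         features = feats[mask], fitness = fitness,
         evaluations = as.integer(evaluations), seed = as.integer(seed)),
    class = "selection_result"
  )
}

#' Apply a feature mask to a matrix
#'
#' @param m Feature matrix tibble.
#' @param mask Logical vector over the non-label columns, or a
#'   `selection_result`.
#' @return The reduced feature matrix (label column kept).
#' @export
mask_matrix <- function(m, mask) {
  if (inherits(mask, "selection_result")) mask <- mask$mask
  feats <- setdiff(names(m), "label")
  stopifnot(length(mask) == length(feats))
  m[c(feats[as.logical(mask)], "label")]
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d/%d features, CV fitness %.4f\n",
              x$method, sum(x$mask), length(x$mask), x$fitness))
  invisible(x)
}

#' @rdname chi_square_select
#' @param x A `selection_result`.
#' @param ... Unused.
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(feature = names(x$mask), selected = unname(x$mask))
}

#' @rdname chi_square_select
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_selected = sum(x$mask),
                 n_features = length(x$mask), fitness = x$fitness,
                 evaluations = x$evaluations, seed = x$seed)
}

#' @rdname chi_square_select
#' @param object A `selection_result`.
#' @export
autoplot.selection_result <- function(object, ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(.data$index, as.integer(.data$selected),
                                  fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "feature index", y = "selected",
                  title = sprintf("%s mask: %d of %d features, fitness %.3f",
                                  object$method, sum(object$mask),
                                  length(object$mask), object$fitness)) +
    ggplot2::theme_minimal()
}
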