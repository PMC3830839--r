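test_that("chi-square matches hand and oracle values", {
  # independence: observed = expected
  expect_identical(bf_chisq(matrix(c(5, 5, 5, 5), 2)), 0)
  expect_equal(sfx:::chi_square_stat(rep(1:2, each = 10),
                                     rep(c("a", "b"), 10)), 0)
  # perfect association [[10,0],[0,10]] -> 20
  x <- rep(1:2, each = 10)
  y <- rep(c("a", "b"), each = 10)
  expect_equal(sfx:::chi_square_stat(x, y), 20)
  expect_equal(bf_chisq(table(x, y)), 20)
  # random tables agree with the textbook oracle
  set.seed(23)
  for (k in 1:20) {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(c("a", "b", "c"), 60, replace = TRUE)
    expect_equal(sfx:::chi_square_stat(x, y), bf_chisq(table(x, y)),
                 tolerance = 1e-9)
    expect_gte(sfx:::chi_square_stat(x, y), 0)
  }
})

test_that("a class-shifted feature outranks noise in nearly every seed", {
  hits <- vapply(1:20, function(s) {
    m <- make_shifted_matrix(n_per_class = 25, informative = 1, noise = 19,
                             shift = 2, seed = s)
    sc <- chi_square_scores(m)
    which.max(sc$score) == 1
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("constant features score zero, not error", {
  m <- make_shifted_matrix(n_per_class = 10, informative = 1, noise = 2)
  m$f3 <- 1
  sc <- chi_square_scores(m)
  expect_identical(sc$score[sc$feature == "f3"], 0)
})

test_that("CFS merit reduces to r_cf at k = 1 and duplicates never help", {
  m <- make_shifted_matrix(n_per_class = 20, informative = 2, noise = 4,
                           seed = 3)
  d <- sfx:::discretize_matrix(m, 10)
  for (j in 1:3) {
    expect_equal(bf_cfs_merit(d$x, d$y, j),
                 bf_su(d$x[, j], d$y), tolerance = 1e-12)
  }
  # duplicating a single selected feature leaves the merit unchanged
  # (r_ff = 1 case): k * rcf / sqrt(k + k(k-1)) = rcf at k = 2
  xd <- cbind(d$x, dup = d$x[, 1])
  expect_equal(bf_cfs_merit(xd, d$y, c(1, ncol(xd))),
               bf_cfs_merit(d$x, d$y, 1), tolerance = 1e-12)
  # hence greedy search cannot terminate on a pure duplicated pair: the
  # second copy is never a strict improvement over its twin alone
  m2 <- m
  m2$dup <- m2$f1
  sel <- cfs_select(m2, sfx_classifier("centroid"), seed = 1)
  expect_false(setequal(sel$features, c("f1", "dup")))
})

test_that("greedy CFS reaches >= 95% of the exhaustive-search merit", {
  # 5 seeded trials here; the full 20-trial experiment runs in the
  # acceptance suite
  for (s in 1:5) {
    m <- make_shifted_matrix(n_per_class = 15, informative = 2, noise = 5,
                             shift = 1.5, seed = 100 + s)
    sel <- cfs_select(m, sfx_classifier("centroid"), seed = s)
    d <- sfx:::discretize_matrix(m, 10)
    u <- ncol(d$x)
    best <- 0
    for (mask_int in 1:(2^u - 1)) {
      subset <- which(bitwAnd(mask_int, 2^(0:(u - 1))) > 0)
      best <- max(best, bf_cfs_merit(d$x, d$y, subset))
    }
    expect_gte(sel$merit, 0.95 * best)
  }
})

test_that("mRMR's first pick maximises relevance and matches stepwise brute force", {
  for (s in 1:5) {
    m <- make_shifted_matrix(n_per_class = 15, informative = 2, noise = 4,
                             shift = 1.5, seed = 200 + s)
    sel <- mrmr_select(m, target_k = 3, seed = s)
    d <- sfx:::discretize_matrix(m, 10)
    u <- ncol(d$x)
    rel <- vapply(seq_len(u), function(j) bf_mi(d$x[, j], d$y), numeric(1))
    # stepwise brute-force reconstruction of the greedy sequence
    expected <- which.max(rel)
    while (length(expected) < 3) {
      cand <- setdiff(seq_len(u), expected)
      crit <- vapply(cand, function(j) {
        rel[j] - mean(vapply(expected, function(i) {
          bf_mi(d$x[, j], d$x[, i])
        }, numeric(1)))
      }, numeric(1))
      expected <- c(expected, cand[which.max(crit)])
    }
    expect_identical(sel$order, expected)
  }
})

test_that("a duplicated feature is not selected while distinct ones remain", {
  m <- make_shifted_matrix(n_per_class = 20, informative = 3, noise = 2,
                           shift = 1.5, seed = 7)
  m$dup <- m$f1
  m <- m[c("f1", "dup", "f2", "f3", "f4", "f5", "label")]
  sel <- mrmr_select(m, target_k = 4, seed = 1)
  # redundancy I(f1, dup) = H(f1) dominates: the pair is never taken while
  # distinct informative features remain
  expect_false(all(c("f1", "dup") %in% sel$features))
})

test_that("WSA is elitist, reproducible and repairs empty masks", {
  m <- make_shifted_matrix(n_per_class = 10, informative = 1, noise = 5,
                           shift = 3, seed = 5)
  cfg <- sfx_config(cv_folds = 5)
  sel1 <- wsa_select(m, sfx_classifier("centroid"), cfg, seed = 2,
                     n_wolves = 5, iterations = 8)
  sel2 <- wsa_select(m, sfx_classifier("centroid"), cfg, seed = 2,
                     n_wolves = 5, iterations = 8)
  expect_identical(sel1$mask, sel2$mask)
  expect_identical(sel1$fitness, sel2$fitness)
  expect_true(all(diff(sel1$trace) >= 0))  # best-so-far never decreases
  expect_gte(sum(sel1$mask), 1)
})

test_that("WSA finds the exhaustive optimum on a 6-feature problem", {
  m <- make_shifted_matrix(n_per_class = 20, informative = 2, noise = 4,
                           shift = 1.2, seed = 9)
  clf <- sfx_classifier("centroid")
  cfg <- sfx_config(cv_folds = 5)
  hits <- vapply(1:20, function(s) {
    # exhaustive optimum under the same folds this run evaluates with
    fold_id <- make_folds(m$label, 5, seed = s)
    optimum <- max(vapply(1:63, function(mask_int) {
      mask <- bitwAnd(mask_int, 2^(0:5)) > 0
      cross_validate(mask_matrix(m, mask), clf,
                     fold_id = fold_id)$accuracy
    }, numeric(1)))
    sel <- wsa_select(m, clf, cfg, seed = s, n_wolves = 10,
                      iterations = 30)
    sel$fitness >= optimum - 1e-12
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("the ensemble is a winner-take-all argmax with documented tie-breaks", {
  m <- make_shifted_matrix(n_per_class = 15, informative = 2, noise = 6,
                           shift = 2, seed = 4)
  clf <- sfx_classifier("centroid")
  cfg <- sfx_config(cv_folds = 5)
  single <- ensemble_select(m, methods = "mrmr", classifier = clf,
                            config = cfg, seed = 1)
  alone <- mrmr_select(m, classifier = clf, config = cfg, seed = 1)
  expect_identical(single$mask, alone$mask)

  ens <- ensemble_select(m, methods = c("chi2", "cfs", "mrmr"),
                         classifier = clf, config = cfg, seed = 1)
  expect_gte(ens$fitness, max(ens$comparison$fitness) - 1e-12)
  # ties break toward fewer features, then method order
  tied <- ens$comparison[ens$comparison$fitness ==
                           max(ens$comparison$fitness), ]
  expect_identical(sum(ens$mask), as.integer(min(tied$n_selected)))

  expect_error(ensemble_select(m, methods = "bogus"), "unknown methods")
})

test_that("selection results are valid against the matrix and tidy-able", {
  m <- make_shifted_matrix(n_per_class = 15, informative = 1, noise = 5)
  sel <- chi_square_select(m, sfx_classifier("centroid"), seed = 1)
  expect_length(sel$mask, ncol(m) - 1L)
  expect_gte(sel$fitness, 0)
  expect_lte(sel$fitness, 1)
  td <- tidy(sel)
  expect_identical(nrow(td), ncol(m) - 1L)
  gl <- glance(sel)
  expect_identical(gl$n_selected, sum(sel$mask))
  reduced <- mask_matrix(m, sel)
  expect_identical(ncol(reduced), sum(sel$mask) + 1L)
})
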