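test_that("the classifier contract holds for all three built-ins", {
  m <- withr::with_seed(1, {
    tibble::tibble(
      x1 = c(rnorm(20), rnorm(20) + 10),
      x2 = c(rnorm(20), rnorm(20) + 10),
      label = rep(c("lo", "hi"), each = 20)
    )
  })
  for (type in c("tree", "centroid", "lda")) {
    f <- fit(sfx_classifier(type), m)
    pred <- predict(f, m)
    expect_identical(pred, m$label)  # linearly separable point clouds
    sc <- predict(f, m, type = "score")
    expect_identical(dim(sc), c(40L, 2L))
    expect_setequal(colnames(sc), c("lo", "hi"))
    expect_true(all(sc >= 0 & sc <= 1))
  }
})

test_that("the tree reproduces a noiseless threshold rule", {
  m <- tibble::tibble(x1 = seq(-2, 2, length.out = 60),
                      x2 = 0,
                      label = ifelse(seq(-2, 2, length.out = 60) > 0,
                                     "A", "B"))
  f <- fit(sfx_classifier("tree"), m)
  expect_identical(predict(f, m), m$label)
})

test_that("fits are deterministic and feature mismatch is caught", {
  m <- make_shifted_matrix(n_per_class = 15, informative = 1, noise = 3)
  f1 <- fit(sfx_classifier("tree", seed = 5), m)
  f2 <- fit(sfx_classifier("tree", seed = 5), m)
  expect_identical(predict(f1, m), predict(f2, m))
  expect_error(predict(f1, m[c("f1", "label")]), "do not match")
})

test_that("cross-validation is stratified, seeded and leak-free", {
  m <- make_shifted_matrix(n_per_class = 20, informative = 2, noise = 2,
                           shift = 8)
  cv <- cross_validate(m, sfx_classifier("centroid"), folds = 5, seed = 1)
  expect_identical(cv$accuracy, 1)  # trivially separable
  expect_identical(length(cv$fold_id), 40L)
  # stratification: each fold has both classes
  for (f in 1:5) {
    expect_setequal(unique(m$label[cv$fold_id == f]), c("a", "b"))
  }
  # seeded fold assignment is stable
  cv2 <- cross_validate(m, sfx_classifier("centroid"), folds = 5, seed = 1)
  expect_identical(cv$fold_id, cv2$fold_id)
  expect_error(cross_validate(m, folds = 25), "at least 25")
})

test_that("permuted labels give chance-level CV accuracy", {
  accs <- vapply(1:20, function(s) {
    m <- make_shifted_matrix(n_per_class = 25, informative = 2, noise = 2,
                             shift = 5, seed = s)
    m$label <- withr::with_seed(1000 + s, sample(m$label))
    cross_validate(m, sfx_classifier("centroid"), folds = 5,
                   seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})
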