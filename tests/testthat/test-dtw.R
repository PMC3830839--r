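test_that("DTW identities and hand examples", {
  set.seed(14)
  x <- rnorm(20)
  expect_identical(dtw(x, x), 0)
  expect_identical(dtw(c(1, 2, 3), c(1, 2, 2, 3)), 0)
  expect_identical(dtw(0, 3), 3)
  expect_error(dtw(numeric(0), 1), "non-empty")
  expect_error(dtw(c(1, NA), 1), "finite")
})

test_that("DTW equals brute-force path enumeration on 200 random pairs", {
  set.seed(15)
  for (k in 1:200) {
    x <- round(rnorm(sample(1:8, 1)), 2)
    y <- round(rnorm(sample(1:8, 1)), 2)
    expect_equal(dtw(x, y), bf_dtw(x, y), tolerance = 1e-12)
  }
})

test_that("DTW is symmetric and bounded by the Euclidean-path cost", {
  set.seed(16)
  for (k in 1:50) {
    n <- sample(3:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(dtw(x, y), dtw(y, x), tolerance = 1e-12)
    expect_lte(dtw(x, y), sum(abs(x - y)) + 1e-12)
  }
})

test_that("mean-pooling preserves length contract and shape", {
  x <- sin(seq(0, 10, length.out = 1234))
  d <- downsample_series(x, 100)
  expect_length(d, 100)
  expect_identical(downsample_series(x, 2000), x)
  expect_error(downsample_series(x, 1), ">= 2")
  # pooled means track the slow shape
  expect_gt(cor(d, sin(seq(0, 10, length.out = 100))), 0.99)
})

test_that("class-distance features equal brute-force pair means", {
  set.seed(17)
  waves <- list()
  for (cl in c("a", "b")) {
    for (i in 1:3) {
      waves[[length(waves) + 1]] <-
        waveform(rnorm(8), 100, label = cl,
                 source_id = paste0(cl, i))
    }
  }
  refs <- as_corpus(waves)
  q <- waveform(rnorm(8), 100, label = "a", source_id = "query")
  f <- class_dtw_features(q, refs, sfx_config(dtw_downsample = 50))
  for (cl in c("a", "b")) {
    rows <- which(refs$label == cl)
    exp_val <- mean(vapply(rows, function(i) {
      bf_dtw(q$samples, refs$samples[[i]])
    }, numeric(1)))
    expect_equal(unname(f[paste0("dtw_class_", cl)]), exp_val,
                 tolerance = 1e-12)
  }
})

test_that("a query among the references is excluded from its own class", {
  w1 <- waveform(c(1, 2, 3, 4), 10, label = "a", source_id = "w1")
  w2 <- waveform(c(2, 2, 3, 5), 10, label = "a", source_id = "w2")
  w3 <- waveform(c(9, 9, 9, 9), 10, label = "b", source_id = "w3")
  refs <- as_corpus(list(w1, w2, w3))
  f <- class_dtw_features(w1, refs, sfx_config(dtw_downsample = 50))
  expect_equal(unname(f["dtw_class_a"]), bf_dtw(w1$samples, w2$samples))

  # identical samples under a different id are NOT excluded: distance 0
  twin <- waveform(c(1, 2, 3, 4), 10, label = "a", source_id = "twin")
  f2 <- class_dtw_features(twin, as_corpus(list(w1, w3)),
                           sfx_config(dtw_downsample = 50))
  expect_identical(unname(f2["dtw_class_a"]), 0)

  # excluding the sole member of a class is an error
  expect_error(
    class_dtw_features(w3, refs[refs$label == "b", ],
                       sfx_config(dtw_downsample = 50)),
    "no reference members"
  )
})
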