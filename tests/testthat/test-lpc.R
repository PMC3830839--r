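test_that("lpc_order follows the sample-rate rule of thumb", {
  expect_identical(lpc_order(10000, 2), 12L)
  expect_identical(lpc_order(10000, 3), 13L)
  expect_identical(lpc_order(8000, 2), 10L)
  expect_error(lpc_order(-1), "positive")
})

test_that("compute_lpc recovers AR coefficients and rejects degenerate input", {
  set.seed(101)
  x <- as.numeric(arima.sim(list(ar = c(0.75, -0.5)), 50000))
  a <- coef(compute_lpc(x, 2))
  expect_lt(abs(a[1] - 0.75), 0.03)
  expect_lt(abs(a[2] - (-0.5)), 0.03)

  set.seed(102)
  wn <- rnorm(50000)
  expect_lt(abs(coef(compute_lpc(wn, 1))), 0.03)

  expect_error(compute_lpc(rep(0, 100), 2), "degenerate")
  expect_error(compute_lpc(rep(3.2, 100), 2), "degenerate")
  expect_error(compute_lpc(1:3, 5), "longer than p")
})

test_that("Levinson-Durbin agrees with a dense Toeplitz solve", {
  set.seed(7)
  for (rep in 1:5) {
    x <- as.numeric(arima.sim(list(ar = c(0.4, -0.3, 0.2)), 2000))
    p <- 6
    r <- sfx:::autocorr(x * sfx:::hamming_window(length(x)), p)
    ld <- sfx:::levinson_durbin(r, p)
    dense <- solve(toeplitz(r[1:p]), r[2:(p + 1)])
    expect_equal(ld$a, dense, tolerance = 1e-9)
  }
})

test_that("the LPC fit minimises the quadratic prediction-error energy", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = c(0.6, -0.2)), 3000))
  p <- 4
  model <- compute_lpc(x, p)
  r <- sfx:::autocorr(x * sfx:::hamming_window(length(x)), p)
  energy <- function(a) {
    r[1] - 2 * sum(a * r[2:(p + 1)]) +
      sum(outer(a, a) * toeplitz(r[1:p]))
  }
  e0 <- energy(model$coefficients)
  for (j in seq_len(p)) {
    for (d in c(-0.01, 0.01)) {
      a2 <- model$coefficients
      a2[j] <- a2[j] + d
      expect_gte(energy(a2), e0 - 1e-12)
    }
  }
})

test_that("cepstral recursion matches hand values and the FFT oracle", {
  # hand evaluation: a = (0.5, 0.25) -> c = (0.5, 0.375)
  model <- structure(list(order = 2, coefficients = c(0.5, 0.25), gain = 1,
                          window = "hamming"), class = "lpc_model")
  cc <- lpc_to_cc(model, 2)
  expect_equal(as.numeric(cc), c(0.5, 0.375))
  expect_equal(as.numeric(cc[1]), model$coefficients[1])  # c_1 = a_1

  # FFT real-cepstrum oracle on a stable fitted model
  set.seed(21)
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 20000))
  fitted <- compute_lpc(x, 12)
  cc10 <- lpc_to_cc(fitted, 10)
  oracle <- fft_lpc_cepstrum(fitted$coefficients, fitted$gain, 10)
  expect_lt(max(abs(cc10 - oracle)) / max(abs(oracle)), 1e-6)
  # c_0 = ln G
  expect_equal(attr(cc10, "c0"), log(fitted$gain), tolerance = 1e-12)
})

test_that("cepstral vector defaults to length 10 and respects n_cc <= p", {
  w <- waveform(sin(2 * pi * 200 * (0:3999) / 10000) +
                  0.1 * sin(2 * pi * 700 * (0:3999) / 10000), 10000)
  cc <- cepstral_features(w)
  expect_length(cc, 10)
  expect_true(all(is.finite(cc)))
  model <- compute_lpc(w$samples, 5)
  expect_error(lpc_to_cc(model, 10), "must not exceed")
})
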