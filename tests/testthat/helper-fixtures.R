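# Small programmatic fixtures shared across test files.

# A compact config that keeps GARCH/DTW work desk-scale in unit tests.
tiny_config <- function(...) {
  sfx_config(n_seg = 5, dtw_downsample = 60, ...)
}

tiny_corpus <- function(n_per_class = 3, n_samples = 600, seed = 11) {
  synth_dataset(synth_preset("fm-like", n_per_class = n_per_class,
                             n_samples = n_samples, seed = seed))
}

# Labelled feature matrix with `informative` class-shifted features in
# front of `noise` pure-noise features; two balanced classes.
make_shifted_matrix <- function(n_per_class = 30, informative = 1,
                                noise = 19, shift = 2, sd_noise = 1,
                                seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    y <- rep(c("a", "b"), each = n_per_class)
    x <- matrix(rnorm(n * (informative + noise), sd = sd_noise), nrow = n)
    for (j in seq_len(informative)) {
      x[y == "b", j] <- x[y == "b", j] + shift
    }
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    out <- tibble::as_tibble(as.data.frame(x))
    out$label <- y
    out
  })
}

# Write a stereo 16-bit PCM WAV (for multichannel error tests).
write_stereo_wav <- function(left, right, rate, path) {
  inter <- as.vector(rbind(as.integer(round(left * 32767)),
                           as.integer(round(right * 32767))))
  n_bytes <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}
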