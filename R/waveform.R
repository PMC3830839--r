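#' Construct a waveform
#'
#' A waveform is a univariate amplitude series with a sample rate, an
#' optional class label, and a source identifier.  It is the unit of input
#' for every feature extractor in the package.
#'
#' @param samples Numeric vector of amplitudes (dimensionless, typically in
#'   `[-1, 1]`).  Must be non-empty and finite.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param label Optional class label (character).
#' @param source_id Identifier of the source recording; used to recognise a
#'   waveform among DTW references (identity, not position).
#'
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 50 * seq(0, 1, length.out = 1000)), 1000)
#' w
#' @export
waveform <- function(samples, sample_rate, label = NA_character_,
                     source_id = "w") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("waveform must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("waveform samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         label = as.character(label), source_id = as.character(source_id)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform '%s'> %d samples @ %g Hz (%.3f s)%s\n",
    x$source_id, length(x$samples), x$sample_rate,
    length(x$samples) / x$sample_rate,
    if (is.na(x$label)) "" else paste0(", label = ", x$label)
  ))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

# Coerce numeric vectors / waveforms uniformly inside extractors.
as_samples <- function(x) {
  if (inherits(x, "waveform")) x$samples else as.numeric(x)
}

#' Convert a corpus tibble to a list of waveforms (and back)
#'
#' A corpus is a tibble with columns `id`, `label`, `sample_rate` and a
#' list-column `samples`; it is the tabular form every corpus-level verb in
#' the package takes and returns.
#'
#' @param waves A list of [waveform()] objects.
#' @return `as_corpus()` returns a corpus tibble; `corpus_waveform()`
#'   rebuilds the `i`-th row as a `waveform`.
#' @export
as_corpus <- function(waves) {
  stopifnot(length(waves) >= 1L)
  tibble::tibble(
    id = vapply(waves, function(w) w$source_id, character(1)),
    label = vapply(waves, function(w) w$label, character(1)),
    sample_rate = vapply(waves, function(w) w$sample_rate, numeric(1)),
    samples = lapply(waves, function(w) w$samples)
  )
}

#' @rdname as_corpus
#' @param corpus A corpus tibble.
#' @param i Row index.
#' @export
corpus_waveform <- function(corpus, i) {
  waveform(corpus$samples[[i]], corpus$sample_rate[[i]],
           corpus$label[[i]], corpus$id[[i]])
}

check_corpus <- function(corpus) {
  need <- c("id", "label", "sample_rate", "samples")
  if (!is.data.frame(corpus) || !all(need %in% names(corpus))) {
    stop("a corpus must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(corpus$id)) {
    stop("corpus ids must be unique", call. = FALSE)
  }
  invisible(corpus)
}

#' Read a mono PCM WAV file
#'
#' Parses a RIFF/WAVE file into a [waveform()].  Integer PCM at 8, 16, 24
#' or 32 bits and 32-bit IEEE float are supported; amplitudes are rescaled
#' to `[-1, 1]`.  Multichannel files are an error unless `mix = TRUE`, in
#' which case channels are averaged.
#'
#' @param path Path to the WAV file.
#' @param label Optional class label to attach.
#' @param mix Average channels of a multichannel file instead of erroring.
#' @return A [waveform()] with `sample_rate` taken from the header.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, label = NA_character_, mix = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2L)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        rate     = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                           endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  }
  if (!fmt$format %in% c(1L, 3L)) {
    stop("unsupported WAV encoding (format tag ", fmt$format,
         "); only PCM and float are read", call. = FALSE)
  }
  if (length(data_raw) == 0L) stop("empty audio data", call. = FALSE)

  x <- decode_pcm(data_raw, fmt$format, fmt$bits)
  if (fmt$channels > 1L) {
    if (!mix) {
      stop("multichannel WAV; pass mix = TRUE to average channels",
           call. = FALSE)
    }
    n <- length(x) %/% fmt$channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels,
                         byrow = TRUE))
  }
  waveform(x, fmt$rate, label = label,
           source_id = tools::file_path_sans_ext(basename(path)))
}

decode_pcm <- function(raw, format, bits) {
  if (format == 3L) {
    if (bits != 32L) stop("float WAV must be 32-bit", call. = FALSE)
    return(readBin(raw, "double", length(raw) %/% 4L, size = 4,
                   endian = "little"))
  }
  switch(
    as.character(bits),
    "8"  = (readBin(raw, "integer", length(raw), size = 1, signed = FALSE) -
              128) / 128,
    "16" = readBin(raw, "integer", length(raw) %/% 2L, size = 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(raw) %/% 3L
      b <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = readBin(raw, "integer", length(raw) %/% 4L, size = 4,
                   endian = "little") / 2147483648,
    stop("unsupported PCM bit depth: ", bits, call. = FALSE)
  )
}

#' Write a waveform as 16-bit mono PCM WAV
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmin(pmax(w$samples, -1), 1)
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  rate <- as.integer(round(w$sample_rate))
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a plain numeric series from CSV
#'
#' The file must contain a single column headed `amplitude`.
#'
#' @inheritParams read_wav
#' @param sample_rate Sample rate to attach (Hz), since CSV carries none.
#' @return A [waveform()].
#' @export
read_series_csv <- function(path, sample_rate, label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"amplitude" %in% names(d)) {
    stop("series CSV must have an 'amplitude' column", call. = FALSE)
  }
  waveform(d$amplitude, sample_rate, label = label,
           source_id = tools::file_path_sans_ext(basename(path)))
}

#' Read a corpus from a manifest CSV
#'
#' The manifest has columns `path,label`; each path is a mono WAV file
#' resolved relative to the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A corpus tibble (see [as_corpus()]).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  man <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("path", "label") %in% names(man))) {
    stop("manifest must have columns path,label", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  waves <- purrr::map2(man$path, as.character(man$label), function(p, lab) {
    full <- if (file.exists(p)) p else file.path(base, p)
    read_wav(full, label = lab)
  })
  as_corpus(waves)
}
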