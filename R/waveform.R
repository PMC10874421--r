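#' Waveform objects
#'
#' A `waveform` is the package's container for a mono speech signal: a numeric
#' amplitude vector in `[-1, 1]`, its sampling rate in Hz, and an opaque
#' `source_id` used to key downstream feature tables and supervectors.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz (positive).
#' @param source_id recording identifier (character scalar).
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate, source_id = "unknown") {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         source_id = as.character(source_id)),
    class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform '%s': %d samples @ %g Hz (%.3f s), peak %.4g>\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param w a `waveform`.
#' @return duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$sample_rate

#' Preprocess a waveform: DC removal, peak normalization, resampling
#'
#' Removes the DC offset (subtracts the sample mean), rescales so that the
#' largest absolute amplitude is 1, and resamples to `target_rate` using
#' polyphase rational resampling. An all-zero signal is returned unchanged
#' (resampled only) with attribute `all_zero = TRUE` and a warning.
#' The operation is idempotent: applying it twice equals applying it once.
#'
#' @param w a `waveform`.
#' @param target_rate target sampling rate in Hz; default 16000.
#' @return a preprocessed `waveform` at `target_rate`.
#' @export
preprocess_waveform <- function(w, target_rate = 16000) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  if (length(x) == 0L) stop("empty waveform: '", w$source_id, "'")
  if (w$sample_rate != target_rate) {
    fr <- .rational_ratio(target_rate, w$sample_rate)
    n_out <- round(length(x) * target_rate / w$sample_rate)
    x <- signal::resample(x, fr[1L], fr[2L])
    # signal::resample can come back one sample long/short of the exact count
    if (length(x) > n_out) x <- x[seq_len(n_out)]
    if (length(x) < n_out) x <- c(x, rep(0, n_out - length(x)))
  }
  peak <- max(abs(x))
  if (peak == 0) {
    warning("all-zero signal: '", w$source_id, "'")
    out <- waveform(x, target_rate, w$source_id)
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  x <- x - mean(x)
  x <- x / max(abs(x))
  out <- waveform(x, target_rate, w$source_id)
  attr(out, "all_zero") <- FALSE
  out
}

# small continued-fraction rational approximation p/q ~= a/b in lowest terms
.rational_ratio <- function(a, b) {
  g <- function(p, q) if (q == 0) p else g(q, p %% q)
  if (a == round(a) && b == round(b)) {
    d <- g(round(a), round(b))
    return(c(round(a) / d, round(b) / d))
  }
  r <- a / b
  best <- c(round(r * 1e6), 1e6)
  d <- g(best[1L], best[2L])
  best / d
}

#' Read a RIFF/WAVE audio file
#'
#' Minimal PCM reader supporting 8/16/24/32-bit integer and 32/64-bit IEEE
#' float encodings. Multichannel input is downmixed to mono by averaging.
#'
#' @param path path to a `.wav` file.
#' @param source_id identifier to attach; defaults to the file name.
#' @return a `waveform` (amplitudes scaled to `[-1, 1]` for integer PCM).
#' @export
read_wav <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = .le_u16(fmt_raw[1:2]),
        channels     = .le_u16(fmt_raw[3:4]),
        sample_rate  = .le_u32(fmt_raw[5:8]),
        bits         = .le_u16(fmt_raw[15:16]))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  x <- .decode_pcm(data_raw, fmt$audio_format, fmt$bits)
  if (length(x) == 0L) stop("empty audio data: ", path)
  if (fmt$channels > 1L) {
    n <- (length(x) %/% fmt$channels) * fmt$channels
    x <- rowMeans(matrix(x[seq_len(n)], ncol = fmt$channels, byrow = TRUE))
  }
  waveform(x, fmt$sample_rate, source_id)
}

.le_u16 <- function(r) as.integer(r[1L]) + 256L * as.integer(r[2L])
.le_u32 <- function(r) sum(as.numeric(as.integer(r)) * 256^(0:3))

.decode_pcm <- function(raw, fmt_code, bits) {
  if (fmt_code == 3L) {  # IEEE float
    return(readBin(raw, "double", length(raw) %/% (bits / 8L),
                   size = bits / 8L, endian = "little"))
  }
  if (fmt_code != 1L) stop("unsupported WAVE format code: ", fmt_code)
  if (bits == 8L) {  # unsigned
    (as.numeric(readBin(raw, "integer", length(raw), 1L, signed = FALSE)) - 128) / 128
  } else if (bits == 16L) {
    readBin(raw, "integer", length(raw) %/% 2L, 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (bits == 24L) {
    n <- length(raw) %/% 3L
    b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else if (bits == 32L) {
    readBin(raw, "integer", length(raw) %/% 4L, 4L, signed = TRUE,
            endian = "little") / 2^31
  } else stop("unsupported PCM bit depth: ", bits)
}

#' Write a waveform as 16-bit PCM WAVE
#'
#' @param w a `waveform`; amplitudes are clipped to `[-1, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(-1, pmin(1, w$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")                 # PCM, mono
  writeBin(as.integer(w$sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(w$sample_rate * 2L), con, 4L, endian = "little")
  writeBin(c(2L, 16L), con, 2L, endian = "little")                # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Load an audio file and preprocess it
#'
#' Convenience composition of [read_wav()] and [preprocess_waveform()]:
#' reads, downmixes, removes DC offset, peak-normalizes, and resamples to
#' 16 kHz.
#'
#' @inheritParams read_wav
#' @param target_rate target sampling rate in Hz.
#' @return a preprocessed `waveform`.
#' @export
load_and_preprocess <- function(path, source_id = basename(path),
                                target_rate = 16000) {
  preprocess_waveform(read_wav(path, source_id), target_rate)
}
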