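#' Fundamental frequency estimation by windowed autocorrelation
#'
#' Frame-wise F0 tracker in the style of Praat's autocorrelation method: each
#' analysis frame is mean-removed, Hann-windowed, and its autocorrelation
#' (computed via FFT) is divided by the autocorrelation of the window to undo
#' the taper bias. The highest normalized peak in the candidate lag range is
#' refined by parabolic interpolation; a frame is voiced when the peak
#' strength exceeds `voicing_threshold`. Unvoiced frames carry `f0 = 0`.
#'
#' @param w a `waveform`.
#' @param fmin,fmax pitch search range in Hz (defaults 60-400, bracketing
#'   adult speech).
#' @param frame_len analysis frame length in seconds (default 0.04).
#' @param hop frame shift in seconds (default 0.01).
#' @param voicing_threshold minimum normalized autocorrelation peak strength
#'   for a voiced decision (default 0.45).
#' @param octave_cost candidate-score penalty per octave of lag, favouring
#'   the true period over its subharmonics when their peaks are comparable
#'   (default 0.10).
#' @param silence_threshold frames whose root-mean-square amplitude falls
#'   below this fraction of the loudest frame are unvoiced (default 0.03).
#' @return An object of class `f0_contour`: a list with `frame_times`
#'   (frame centers, seconds), `f0` (Hz; 0 = unvoiced), `strength`, and the
#'   framing parameters in samples.
#' @export
estimate_f0 <- function(w, fmin = 60, fmax = 400, frame_len = 0.04,
                        hop = 0.01, voicing_threshold = 0.45,
                        octave_cost = 0.10, silence_threshold = 0.03) {
  stopifnot(inherits(w, "waveform"), fmin > 0, fmin < fmax,
            fmax < w$sample_rate / 2)
  sr <- w$sample_rate
  flen <- round(frame_len * sr)
  hlen <- round(hop * sr)
  x <- w$samples
  nfr <- if (length(x) < flen) 0L else (length(x) - flen) %/% hlen + 1L
  out <- structure(
    list(frame_times = numeric(nfr), f0 = numeric(nfr), strength = numeric(nfr),
         frame_len = flen, hop = hlen, sample_rate = sr, n_samples = length(x)),
    class = "f0_contour")
  if (nfr == 0L) return(out)

  starts <- (seq_len(nfr) - 1L) * hlen          # 0-based frame starts
  out$frame_times <- (starts + flen / 2) / sr
  idx <- outer(seq_len(flen), starts, "+")      # flen x nfr, 1-based
  fr <- matrix(x[idx], nrow = flen)
  fr <- sweep(fr, 2L, colMeans(fr))
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 1L) / (flen - 1L))
  nfft <- 2^ceiling(log2(2L * flen))

  acf_of <- function(m) {
    pad <- rbind(m, matrix(0, nfft - nrow(m), ncol(m)))
    sp <- stats::mvfft(pad)
    Re(stats::mvfft(sp * Conj(sp), inverse = TRUE)) / nfft
  }
  ac <- acf_of(fr * win)
  acw <- acf_of(matrix(win, ncol = 1L))
  lag_min <- max(2L, floor(sr / fmax))
  lag_max <- min(ceiling(sr / fmin), flen - 2L)
  lags <- lag_min:lag_max
  # normalized, window-corrected autocorrelation per frame
  r0 <- ac[1L, ]
  rms <- sqrt(colMeans(fr^2))
  live <- r0 > 1e-14 & rms >= silence_threshold * max(rms)
  wcorr <- acw[lags + 1L, 1L] / acw[1L, 1L]
  for (k in which(live)) {
    r <- (ac[lags + 1L, k] / r0[k]) / wcorr
    # interior local maxima only; subharmonic peaks pay an octave cost
    pk <- which(diff(sign(diff(r))) == -2) + 1L
    pk <- pk[is.finite(r[pk]) & r[pk] >= voicing_threshold]
    if (!length(pk)) next
    score <- r[pk] - octave_cost * log2(lags[pk] / lags[1L])
    j <- pk[which.max(score)]
    strength <- r[j]
    lag <- lags[j]
    # parabolic refinement over the uncorrected ACF neighbourhood
    ym <- ac[lag, k]; y0 <- ac[lag + 1L, k]; yp <- ac[lag + 2L, k]
    den <- ym - 2 * y0 + yp
    d <- if (abs(den) > 1e-30) 0.5 * (ym - yp) / den else 0
    d <- max(-0.5, min(0.5, d))
    f0 <- sr / (lag + d)
    if (f0 < fmin || f0 > fmax) next
    out$f0[k] <- f0
    out$strength[k] <- min(strength, 1)
  }
  .smooth_voicing(out)
}

# contour cleanup: a voiced frame with unvoiced neighbours on both sides is
# spurious and dropped; a single unvoiced frame inside a voiced run is a
# tracking dropout and gets the mean of its neighbours
.smooth_voicing <- function(contour) {
  f0 <- contour$f0
  n <- length(f0)
  if (n >= 3L) {
    v <- f0 > 0
    prev_v <- c(FALSE, v[-n]); next_v <- c(v[-1L], FALSE)
    iso <- v & !prev_v & !next_v
    f0[iso] <- 0
    contour$strength[iso] <- 0
    v <- f0 > 0
    prev_v <- c(FALSE, v[-n]); next_v <- c(v[-1L], FALSE)
    gap <- !v & prev_v & next_v
    idx <- which(gap)
    f0[idx] <- (f0[idx - 1L] + f0[idx + 1L]) / 2
  }
  contour$f0 <- f0
  contour
}

#' @export
print.f0_contour <- function(x, ...) {
  nv <- sum(x$f0 > 0)
  cat(sprintf("<f0_contour: %d frames, %d voiced (%.0f%%)%s>\n",
              length(x$f0), nv, if (length(x$f0)) 100 * nv / length(x$f0) else 0,
              if (nv) sprintf(", median F0 %.1f Hz", stats::median(x$f0[x$f0 > 0]))
              else ""))
  invisible(x)
}

# maximal runs of voiced frames; returns 0-based inclusive frame index ranges
.voiced_runs <- function(f0) {
  v <- f0 > 0
  if (!any(v)) return(matrix(integer(0), ncol = 2L))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(starts[keep] - 1L, ends[keep] - 1L)
}

#' Voiced segments of a waveform
#'
#' Maximal runs of consecutive voiced frames in an F0 contour, mapped to
#' 0-based half-open sample intervals covering every analysis window of the
#' run. Runs shorter than `min_dur` seconds are discarded.
#'
#' @param contour an `f0_contour` computed on `w`.
#' @param w the `waveform` the contour was computed on.
#' @param min_dur minimum segment duration in seconds (default 0.04: a
#'   segment must host at least one full analysis frame).
#' @return A list of `voiced_segment` objects with fields `start_sample`,
#'   `end_sample` (0-based half-open), `start_frame`, `end_frame` (0-based
#'   inclusive), `f0_track`, `duration`.
#' @export
voiced_segments <- function(contour, w, min_dur = 0.04) {
  stopifnot(inherits(contour, "f0_contour"), inherits(w, "waveform"),
            contour$sample_rate == w$sample_rate)
  runs <- .voiced_runs(contour$f0)
  n <- length(w$samples)
  segs <- list()
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1L]; b <- runs[i, 2L]
    start <- a * contour$hop
    end <- min(b * contour$hop + contour$frame_len, n)
    dur <- (end - start) / w$sample_rate
    if (dur < min_dur) next
    segs[[length(segs) + 1L]] <- structure(
      list(start_sample = start, end_sample = end,
           start_frame = a, end_frame = b,
           f0_track = contour$f0[(a:b) + 1L],
           duration = dur),
      class = "voiced_segment")
  }
  segs
}

#' Unvoiced-to-voiced onset segments
#'
#' One segment per unvoiced-to-voiced border: 40 ms of signal to each side of
#' the border (80 ms total; 1280 samples at 16 kHz). Borders within 40 ms of
#' either signal edge are dropped rather than zero-padded, and a voiced
#' segment starting at the first frame yields no onset. Voiced-to-unvoiced
#' transitions (offsets) are not extracted.
#'
#' @inheritParams voiced_segments
#' @param half_width context taken on each side of the border, seconds
#'   (default 0.04).
#' @return A list of `onset_segment` objects with fields `border_sample`
#'   (0-based), `samples` (the 80 ms excerpt), `start_sample`, `end_sample`.
#' @export
onset_segments <- function(contour, w, min_dur = 0.04, half_width = 0.04) {
  segs <- voiced_segments(contour, w, min_dur)
  hw <- round(half_width * w$sample_rate)
  n <- length(w$samples)
  out <- list()
  for (s in segs) {
    if (s$start_frame == 0L) next                    # voiced from the edge
    border <- s$start_sample
    if (border - hw < 0L || border + hw > n) next
    out[[length(out) + 1L]] <- structure(
      list(border_sample = border,
           samples = w$samples[(border - hw + 1L):(border + hw)],
           start_sample = border - hw, end_sample = border + hw),
      class = "onset_segment")
  }
  out
}

#' Segment table for export
#'
#' Flattens voiced and onset segments into a data frame with columns
#' `source_id`, `kind`, `start_sample`, `end_sample` (0-based half-open),
#' suitable for CSV export.
#'
#' @param w the source `waveform`.
#' @param voiced list of `voiced_segment`s.
#' @param onsets list of `onset_segment`s.
#' @return a data frame.
#' @export
segments_table <- function(w, voiced, onsets) {
  row <- function(kind, s) data.frame(
    source_id = w$source_id, kind = kind,
    start_sample = s$start_sample, end_sample = s$end_sample,
    stringsAsFactors = FALSE)
  rows <- c(lapply(voiced, row, kind = "voiced"),
            lapply(onsets, row, kind = "onset"))
  if (!length(rows))
    return(data.frame(source_id = character(0), kind = character(0),
                      start_sample = integer(0), end_sample = integer(0)))
  do.call(rbind, rows)
}
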