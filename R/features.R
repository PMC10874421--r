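#' Feature matrix container
#'
#' Holds the frame- or segment-level features of one recording in one speech
#' dimension: a numeric `T x D` matrix (`values`) with labeled columns, the
#' dimension name (`articulation`, `phonation`, or `prosody`; `D` = 58, 7, 13
#' respectively), and the recording's `source_id`.
#'
#' @param values numeric matrix, rows = frames or voiced segments.
#' @param dimension one of `"articulation"`, `"phonation"`, `"prosody"`.
#' @param source_id recording identifier.
#' @param frame_times optional vector of row timestamps in seconds.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, dimension, source_id = "unknown",
                           frame_times = NULL) {
  dims <- c(articulation = 58L, phonation = 7L, prosody = 13L)
  dimension <- match.arg(dimension, names(dims))
  values <- as.matrix(values)
  if (nrow(values) > 0L && !all(is.finite(values)))
    stop("non-finite feature values for '", source_id, "' (", dimension, ")")
  if (ncol(values) != dims[[dimension]])
    stop("expected ", dims[[dimension]], " columns for ", dimension,
         ", got ", ncol(values))
  structure(list(values = values, dimension = dimension,
                 source_id = source_id, frame_times = frame_times),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix '%s' [%s]: %d x %d>\n",
              x$source_id, x$dimension, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# accept either a feature_matrix or a bare numeric matrix
.fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

#' Bark critical-band partition of the spectrum
#'
#' Band edges in Hz for `n_bands` contiguous critical bands spanning
#' `[0, sr/2]`, equally spaced on Traunmueller's Bark scale
#' `z(f) = 26.81 f / (1960 + f) - 0.53`.
#'
#' @param sr sampling rate in Hz.
#' @param n_bands number of bands (default 22).
#' @return numeric vector of `n_bands + 1` edges, first 0, last `sr/2`.
#' @export
bark_band_edges <- function(sr = 16000, n_bands = 22L) {
  bark <- function(f) 26.81 * f / (1960 + f) - 0.53
  inv_bark <- function(z) 1960 * (z + 0.53) / (26.28 - z)
  z <- seq(bark(0), bark(sr / 2), length.out = n_bands + 1L)
  edges <- inv_bark(z)
  edges[1L] <- 0
  edges[n_bands + 1L] <- sr / 2
  edges
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

# power spectrum columns for a frame matrix (flen x nframes), Hann-windowed
.power_spectrum <- function(frames, nfft) {
  win <- .hann(nrow(frames))
  pad <- rbind(frames * win, matrix(0, nfft - nrow(frames), ncol(frames)))
  sp <- stats::mvfft(pad)
  (Mod(sp[seq_len(nfft %/% 2L + 1L), , drop = FALSE]))^2
}

#' Bark-band log energies of one analysis frame
#'
#' Energy content of the frame in 22 critical bands on the Bark scale,
#' reported as natural-log energies with floor `log(1e-10)`.
#'
#' @param frame numeric vector, one 40 ms analysis window.
#' @param sr sampling rate in Hz.
#' @param n_bands number of Bark bands (default 22).
#' @param floor lower bound applied to linear band energies before the log.
#' @return numeric vector of `n_bands` log energies.
#' @export
bark_band_energies <- function(frame, sr = 16000, n_bands = 22L,
                               floor = 1e-10) {
  nfft <- 2^ceiling(log2(length(frame)))
  ps <- .power_spectrum(matrix(frame, ncol = 1L), nfft)[, 1L]
  freqs <- (seq_along(ps) - 1L) * sr / nfft
  edges <- bark_band_edges(sr, n_bands)
  band <- findInterval(freqs, edges, rightmost.closed = TRUE)
  band[band < 1L] <- 1L; band[band > n_bands] <- n_bands
  e <- vapply(seq_len(n_bands), function(b) sum(ps[band == b]), numeric(1))
  log(pmax(e, floor))
}

# mel filterbank (n_filters x n_bins) for given fft size
.mel_filterbank <- function(sr, nfft, n_filters = 26L) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(sr / 2), length.out = n_filters + 2L))
  bins <- (seq_len(nfft %/% 2L + 1L) - 1L) * sr / nfft
  fb <- matrix(0, n_filters, length(bins))
  for (i in seq_len(n_filters)) {
    lo <- pts[i]; mid <- pts[i + 1L]; hi <- pts[i + 2L]
    up <- (bins - lo) / (mid - lo)
    down <- (hi - bins) / (hi - mid)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# 12 MFCCs (c1..c12, c0 excluded) per column of a frame matrix
.mfcc_frames <- function(frames, sr, n_coef = 12L, n_filters = 26L,
                         floor = 1e-10) {
  nfft <- 2^ceiling(log2(nrow(frames)))
  ps <- .power_spectrum(frames, nfft)
  fb <- .mel_filterbank(sr, nfft, n_filters)
  loge <- log(pmax(fb %*% ps, floor))              # n_filters x nframes
  j <- seq_len(n_filters)
  dct <- outer(seq_len(n_coef), j,
               function(k, j) cos(pi * k * (j - 0.5) / n_filters))
  t(dct %*% loge)                                  # nframes x n_coef
}

#' Temporal derivative of a feature sequence
#'
#' Central-difference derivative along rows with edge replication:
#' `d[t] = (x[t+1] - x[t-1]) / 2`, with the first and last rows replicated
#' before differencing. Applying it twice gives the second derivative. A
#' single row yields a zero row.
#'
#' @param m numeric `T x K` matrix (or vector, treated as `T x 1`).
#' @return matrix of the same shape.
#' @export
delta_coefficients <- function(m) {
  m <- as.matrix(m)
  t_len <- nrow(m)
  if (t_len == 0L) return(m)
  if (t_len == 1L) return(m * 0)
  ext <- rbind(m[1L, , drop = FALSE], m, m[t_len, , drop = FALSE])
  (ext[3:(t_len + 2L), , drop = FALSE] - ext[1:t_len, , drop = FALSE]) / 2
}

#' Articulation features at voicing onsets
#'
#' For each 80 ms onset segment, frames of 40 ms with a 20 ms shift (3 frames
#' per segment) are characterized by 22 Bark-band log energies and 12 MFCCs;
#' first and second MFCC derivatives are appended, computed within the
#' segment. Rows are concatenated over segments; columns are ordered
#' `[22 Bark | 12 MFCC | 12 dMFCC | 12 ddMFCC]` (58 total).
#'
#' @param onsets list of `onset_segment`s from [onset_segments()].
#' @param sr sampling rate in Hz (16000 in the pipeline).
#' @param source_id recording identifier.
#' @param frame_len,hop framing in seconds (defaults 0.04 / 0.02).
#' @return a `feature_matrix` with `dimension = "articulation"`; row
#'   timestamps (frame starts, seconds) in `$frame_times`.
#' @export
articulation_features <- function(onsets, sr = 16000, source_id = "unknown",
                                  frame_len = 0.04, hop = 0.02) {
  labels <- c(paste0("bark_", 1:22), paste0("mfcc_", 1:12),
              paste0("dmfcc_", 1:12), paste0("ddmfcc_", 1:12))
  flen <- round(frame_len * sr)
  hlen <- round(hop * sr)
  rows <- list(); times <- numeric(0)
  for (seg in onsets) {
    x <- seg$samples
    nfr <- (length(x) - flen) %/% hlen + 1L
    if (nfr < 1L) next
    starts <- (seq_len(nfr) - 1L) * hlen
    fr <- matrix(x[outer(seq_len(flen), starts, "+")], nrow = flen)
    bark <- t(apply(fr, 2L, bark_band_energies, sr = sr))
    mf <- .mfcc_frames(fr, sr)
    d1 <- delta_coefficients(mf)
    d2 <- delta_coefficients(d1)
    rows[[length(rows) + 1L]] <- cbind(bark, mf, d1, d2)
    times <- c(times, (seg$start_sample + starts) / sr)
  }
  values <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0L, 58L)
  colnames(values) <- labels
  feature_matrix(values, "articulation", source_id, frame_times = times)
}

#' Cycle-to-cycle perturbation measures
#'
#' Jitter, shimmer, and the five-point period (PPQ) and eleven-point
#' amplitude (APQ) perturbation quotients from a sequence of glottal-cycle
#' periods and peak amplitudes, all in percent:
#' jitter = mean absolute difference of consecutive periods over the mean
#' period; shimmer is the amplitude analogue; PPQ compares each period to the
#' mean of its 5-point neighbourhood; APQ to its 11-point neighbourhood.
#' With fewer periods than the neighbourhood width, the quotient uses all
#' available periods as the neighbourhood.
#'
#' @param periods numeric vector of cycle periods (any consistent unit).
#' @param amplitudes numeric vector of per-cycle peak amplitudes, same
#'   length as `periods`.
#' @return named numeric vector `c(jitter, shimmer, ppq, apq)` in percent;
#'   `NA` entries when fewer than 2 cycles are available.
#' @export
perturbation_measures <- function(periods, amplitudes) {
  stopifnot(length(periods) == length(amplitudes))
  n <- length(periods)
  rel_diff <- function(v) {
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    100 * mean(abs(diff(v))) / mean(v)
  }
  quotient <- function(v, k) {
    n <- length(v)
    if (n < 2L || mean(v) == 0) return(NA_real_)
    half <- (k - 1L) %/% 2L
    ks <- if (n >= k) (half + 1L):(n - half) else seq_len(n)
    dev <- vapply(ks, function(i) {
      idx <- if (n >= k) (i - half):(i + half) else seq_len(n)
      abs(v[i] - mean(v[idx]))
    }, numeric(1))
    100 * mean(dev) / mean(v)
  }
  c(jitter = rel_diff(periods), shimmer = rel_diff(amplitudes),
    ppq = quotient(periods, 5L), apq = quotient(amplitudes, 11L))
}

# cycle marks: rising zero crossings of the mean-removed signal, selected to
# be ~one local pitch period apart; returns fractional sample positions
.cycle_marks <- function(x, f0_local, sr) {
  x <- x - mean(x)
  s <- sign(x); s[s == 0] <- 1
  cross <- which(s[-length(s)] < 0 & s[-1L] > 0)
  if (length(cross) < 2L) return(numeric(0))
  frac <- cross + x[cross] / (x[cross] - x[cross + 1L])
  period <- function(pos) {
    i <- min(length(f0_local), max(1L, ceiling(pos / length(x) * length(f0_local))))
    f <- f0_local[i]
    if (f <= 0) f <- stats::median(f0_local[f0_local > 0])
    sr / f
  }
  marks <- frac[1L]
  cur <- frac[1L]
  repeat {
    p <- period(cur)
    cand <- frac[frac > cur + 0.6 * p & frac < cur + 1.5 * p]
    if (!length(cand)) {
      nxt <- frac[frac > cur + 1.5 * p]
      if (!length(nxt)) break
      cur <- nxt[1L]
      marks <- c(marks, NA_real_, cur)   # NA marks a break in the train
      next
    }
    cur <- cand[which.min(abs(cand - (cur + p)))]
    marks <- c(marks, cur)
  }
  marks
}

# periods (s) and per-cycle peak amplitudes from a mark train with NA breaks
.cycles_from_marks <- function(x, marks, sr) {
  periods <- numeric(0); amps <- numeric(0)
  if (length(marks) < 2L)
    return(list(periods = periods, amplitudes = amps))
  for (i in seq_len(length(marks) - 1L)) {
    a <- marks[i]; b <- marks[i + 1L]
    if (is.na(a) || is.na(b)) next
    periods <- c(periods, (b - a) / sr)
    lo <- max(1L, ceiling(a)); hi <- min(length(x), floor(b))
    amps <- c(amps, if (hi >= lo) max(abs(x[lo:hi])) else NA_real_)
  }
  ok <- is.finite(periods) & is.finite(amps)
  list(periods = periods[ok], amplitudes = amps[ok])
}

#' Phonation features over voiced segments
#'
#' One 7-vector per voiced segment:
#' `[mean |dF0|, mean |ddF0|, jitter %, shimmer %, APQ %, PPQ %, energy dB]`.
#' F0 derivatives are mean absolute frame-to-frame differences of the
#' segment's F0 track (Hz). Jitter/shimmer/APQ/PPQ come from glottal cycle
#' marks placed at rising zero crossings guided by the local F0. Segments
#' with fewer than 5 detected cycles are dropped.
#'
#' @param voiced list of `voiced_segment`s.
#' @param w the source `waveform`.
#' @param min_periods minimum cycle count to retain a segment (default 5).
#' @return a `feature_matrix` with `dimension = "phonation"`. The number of
#'   dropped segments is recorded in attribute `"n_dropped"` of the result.
#' @export
phonation_features <- function(voiced, w, min_periods = 5L) {
  labels <- c("mean_abs_df0", "mean_abs_ddf0", "jitter_pct", "shimmer_pct",
              "apq_pct", "ppq_pct", "energy_db")
  rows <- list(); dropped <- 0L
  for (seg in voiced) {
    x <- w$samples[(seg$start_sample + 1L):seg$end_sample]
    marks <- .cycle_marks(x, seg$f0_track, w$sample_rate)
    cyc <- .cycles_from_marks(x, marks, w$sample_rate)
    if (length(cyc$periods) < min_periods) { dropped <- dropped + 1L; next }
    pert <- perturbation_measures(cyc$periods, cyc$amplitudes)
    f0 <- seg$f0_track
    df0 <- if (length(f0) >= 2L) mean(abs(diff(f0))) else 0
    ddf0 <- if (length(f0) >= 3L) mean(abs(diff(diff(f0)))) else 0
    energy <- 10 * log10(max(mean(x^2), 1e-10))
    rows[[length(rows) + 1L]] <-
      c(df0, ddf0, pert[["jitter"]], pert[["shimmer"]],
        pert[["apq"]], pert[["ppq"]], energy)
  }
  values <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0L, 7L)
  colnames(values) <- labels
  out <- feature_matrix(values, "phonation", w$source_id)
  attr(out, "n_dropped") <- dropped
  out
}

# monomial coefficients (a0..a5) of the degree-5 polynomial through 6 nodes
.lagrange_coef <- function(u, y) {
  v <- outer(u, 0:5, "^")
  as.numeric(solve(v, y))
}

# least-squares degree-5 fit on normalized time, exact when n == 6
.poly5_fit <- function(u, y) {
  v <- outer(u, 0:5, "^")
  as.numeric(qr.coef(qr(v), y))
}

#' Prosody features over voiced segments
#'
#' One 13-vector per voiced segment:
#' `[duration s | 6 F0-contour coefficients | 6 energy-contour coefficients]`.
#' The F0 contour over the segment (normalized time `u` in `[0, 1]`) is
#' modelled by a degree-5 polynomial: interpolated exactly when the segment
#' has 6 frames, least-squares fitted when it has more. The frame energy
#' contour (dB) is modelled by the degree-5 Lagrange polynomial through its
#' values at 6 equally spaced nodes. Segments with fewer than 6 frames are
#' dropped.
#'
#' @param voiced list of `voiced_segment`s.
#' @param w the source `waveform`.
#' @param frame_len,hop framing used for the energy contour, seconds
#'   (matching the F0 framing: 0.04 / 0.01).
#' @return a `feature_matrix` with `dimension = "prosody"`; attribute
#'   `"n_dropped"` counts discarded short segments.
#' @export
prosody_features <- function(voiced, w, frame_len = 0.04, hop = 0.01) {
  labels <- c("duration_s", paste0("f0_c", 0:5), paste0("en_c", 0:5))
  flen <- round(frame_len * w$sample_rate)
  hlen <- round(hop * w$sample_rate)
  rows <- list(); dropped <- 0L
  for (seg in voiced) {
    nfr <- length(seg$f0_track)
    if (nfr < 6L) { dropped <- dropped + 1L; next }
    u <- seq(0, 1, length.out = nfr)
    f0_coef <- .poly5_fit(u, seg$f0_track)
    x <- w$samples[(seg$start_sample + 1L):seg$end_sample]
    starts <- (seq_len(nfr) - 1L) * hlen
    starts <- starts[starts + flen <= length(x)]
    if (length(starts) < 2L) { dropped <- dropped + 1L; next }
    en <- vapply(starts, function(s)
      10 * log10(max(mean(x[(s + 1L):(s + flen)]^2), 1e-10)), numeric(1))
    ue <- seq(0, 1, length.out = length(en))
    nodes <- seq(0, 1, length.out = 6L)
    node_vals <- stats::approx(ue, en, xout = nodes)$y
    en_coef <- .lagrange_coef(nodes, node_vals)
    rows[[length(rows) + 1L]] <- c(seg$duration, f0_coef, en_coef)
  }
  values <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0L, 13L)
  colnames(values) <- labels
  out <- feature_matrix(values, "prosody", w$source_id)
  attr(out, "n_dropped") <- dropped
  out
}

#' Extract all three speech-dimension feature matrices from a waveform
#'
#' Runs F0 estimation and segmentation, then the articulation (onset-based),
#' phonation, and prosody (voiced-segment-based) extractors.
#'
#' @param w a preprocessed `waveform` (16 kHz).
#' @param fmin,fmax,frame_len,hop,voicing_threshold passed to
#'   [estimate_f0()].
#' @return named list of three `feature_matrix` objects
#'   (`articulation`, `phonation`, `prosody`).
#' @export
extract_features <- function(w, fmin = 60, fmax = 400, frame_len = 0.04,
                             hop = 0.01, voicing_threshold = 0.45) {
  contour <- estimate_f0(w, fmin, fmax, frame_len, hop, voicing_threshold)
  voiced <- voiced_segments(contour, w)
  onsets <- onset_segments(contour, w)
  list(articulation = articulation_features(onsets, w$sample_rate,
                                            w$source_id),
       phonation = phonation_features(voiced, w),
       prosody = prosody_features(voiced, w))
}
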