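test_that("articulation framing: 3 frames x 58 columns per 80 ms onset", {
  w <- waveform(c(make_noise(0.5, seed = 1)$samples,
                  make_tone(140, 0.5)$samples), 16000, "nv")
  on <- onset_segments(estimate_f0(w), w)
  expect_length(on, 1)
  fm <- articulation_features(on, 16000, "nv")
  expect_equal(dim(fm$values), c(3L, 58L))
  expect_equal(colnames(fm$values),
               c(paste0("bark_", 1:22), paste0("mfcc_", 1:12),
                 paste0("dmfcc_", 1:12), paste0("ddmfcc_", 1:12)))
  # frame timestamps advance by exactly 20 ms within the segment
  expect_equal(diff(fm$frame_times), c(0.02, 0.02))
  # empty onset list
  empty <- articulation_features(list(), 16000, "none")
  expect_equal(dim(empty$values), c(0L, 58L))
})

test_that("Bark bands partition [0, 8000] Hz and localize a pure tone", {
  edges <- bark_band_edges(16000, 22)
  expect_length(edges, 23)
  expect_equal(edges[1], 0)
  expect_equal(edges[23], 8000)
  expect_true(all(diff(edges) > 0))

  # oracle: the band holding 250 Hz must carry the maximum energy
  t <- seq_len(640) / 16000
  frame <- sin(2 * pi * 250 * t)
  e <- bark_band_energies(frame, 16000)
  expect_length(e, 22)
  oracle_band <- findInterval(250, edges, rightmost.closed = TRUE)
  expect_equal(which.max(e), oracle_band)

  # all-zero frame sits at the log floor
  expect_true(all(bark_band_energies(numeric(640), 16000) == log(1e-10)))

  # doubling the amplitude shifts every above-floor log energy by log 4
  nz <- make_noise(0.04, seed = 7)$samples
  e1 <- bark_band_energies(nz, 16000)
  e2 <- bark_band_energies(2 * nz, 16000)
  expect_equal(e2 - e1, rep(log(4), 22), tolerance = 1e-9)
})

test_that("a 250 Hz voiced half dominates the matching Bark band", {
  t <- seq_len(640) / 16000
  seg <- structure(list(border_sample = 640,
                        samples = c(numeric(640), sin(2 * pi * 250 * t)),
                        start_sample = 0, end_sample = 1280),
                   class = "onset_segment")
  fm <- articulation_features(list(seg), 16000, "halfsine")
  edges <- bark_band_edges(16000, 22)
  oracle_band <- findInterval(250, edges, rightmost.closed = TRUE)
  # third frame (samples 640-1280) is fully inside the voiced half
  expect_equal(unname(which.max(fm$values[3, 1:22])), oracle_band)
})

test_that("delta coefficients: zero for constants, slope for ramps", {
  const <- matrix(3, 5, 4)
  expect_true(all(delta_coefficients(const) == 0))
  ramp <- outer(1:6, c(1, 2))          # step c per frame, per column
  d <- delta_coefficients(ramp)
  expect_equal(d[2:5, 1], rep(1, 4))
  expect_equal(d[2:5, 2], rep(2, 4))
  expect_equal(delta_coefficients(matrix(1:3, 1)), matrix(0, 1, 3))
  # applying twice is the second derivative; constants vanish again
  expect_true(all(abs(delta_coefficients(delta_coefficients(ramp))[3:4, ]) < 1e-12))
})

test_that("perturbation quotients match their definitions on known cycles", {
  periods <- rep(c(10, 10.2), 10)
  amps <- rep(c(1.1, 0.9), 10)
  p <- perturbation_measures(periods, amps)
  expect_equal(p[["jitter"]], 100 * 0.2 / mean(periods), tolerance = 1e-12)
  expect_equal(p[["shimmer"]], 100 * 0.2 / 1.0, tolerance = 1e-12)
  # constants have zero perturbation
  z <- perturbation_measures(rep(7, 30), rep(2, 30))
  expect_equal(unname(z), rep(0, 4))
  # brute-force oracle for PPQ on a short irregular train
  set.seed(2)
  per <- 10 + stats::runif(12, -0.5, 0.5)
  ppq_oracle <- 100 * mean(vapply(3:10, function(k)
    abs(per[k] - mean(per[(k - 2):(k + 2)])), numeric(1))) / mean(per)
  expect_equal(perturbation_measures(per, per)[["ppq"]], ppq_oracle,
               tolerance = 1e-12)
})

test_that("phonation recovers injected cycle perturbations", {
  # perfectly periodic, constant amplitude: everything near zero
  w <- make_tone(125, dur = 0.8, n_harmonics = 6)
  c <- estimate_f0(w)
  fm <- phonation_features(voiced_segments(c, w), w)
  expect_equal(dim(fm$values)[2], 7L)
  expect_gt(nrow(fm$values), 0)
  expect_lt(fm$values[1, "jitter_pct"], 0.1)
  expect_lt(fm$values[1, "shimmer_pct"], 1)
  expect_lt(fm$values[1, "mean_abs_df0"], 1)

  # alternating 10 / 10.2 ms cycles: jitter by the definition is 1.98 %
  per <- round(rep(c(0.010, 0.0102), 40) * 16000)
  cw <- make_cycle_signal(per)
  cc <- estimate_f0(cw)
  fmc <- phonation_features(voiced_segments(cc, cw), cw)
  expect_equal(unname(fmc$values[1, "jitter_pct"]),
               100 * mean(abs(diff(per))) / mean(per), tolerance = 0.4)

  # +/- 10 % alternating amplitudes: shimmer close to 20 %
  aw <- make_cycle_signal(rep(round(0.008 * 16000), 80),
                          amplitudes = rep(c(1.1, 0.9), 40))
  ca <- estimate_f0(aw)
  fma <- phonation_features(voiced_segments(ca, aw), aw)
  expect_equal(unname(fma$values[1, "shimmer_pct"]), 20, tolerance = 2)
})

test_that("ratio-based perturbation features are amplitude-scale invariant", {
  w <- preprocess_waveform(synth_utterance(synth_profile("et", seed = 4,
                                                         n_syllables = 4L)))
  ws <- waveform(0.2 * w$samples, 16000, w$source_id)
  f1 <- phonation_features(voiced_segments(estimate_f0(w), w), w)
  f2 <- phonation_features(voiced_segments(estimate_f0(ws), ws), ws)
  ratio_cols <- c("jitter_pct", "shimmer_pct", "apq_pct", "ppq_pct")
  expect_equal(f1$values[, ratio_cols], f2$values[, ratio_cols],
               tolerance = 1e-6)
  # energy is not scale invariant: 20 log10(0.2) dB shift
  expect_equal(f2$values[, "energy_db"] - f1$values[, "energy_db"],
               rep(20 * log10(0.2), nrow(f1$values)), tolerance = 1e-6)
})

test_that("prepending 100 ms of silence shifts offsets, not feature values", {
  w <- preprocess_waveform(synth_utterance(synth_profile("hc", seed = 5,
                                                         n_syllables = 4L)))
  wp <- waveform(c(numeric(1600), w$samples), 16000, w$source_id)
  f1 <- extract_features(w)
  f2 <- extract_features(wp)
  for (d in c("articulation", "phonation", "prosody"))
    expect_equal(f1[[d]]$values, f2[[d]]$values, tolerance = 1e-8)
  expect_equal(f2$articulation$frame_times - f1$articulation$frame_times,
               rep(0.1, length(f1$articulation$frame_times)),
               tolerance = 1e-9)
})

test_that("prosody recovers an exact degree-5 F0 polynomial", {
  coefs <- c(120, 15, -40, 60, -30, 5)
  nfr <- 6L
  u <- seq(0, 1, length.out = nfr)
  f0 <- drop(outer(u, 0:5, "^") %*% coefs)
  w <- make_tone(120, dur = 0.2)
  seg <- structure(list(start_sample = 0, end_sample = 1440,
                        start_frame = 0, end_frame = nfr - 1,
                        f0_track = f0, duration = 0.09),
                   class = "voiced_segment")
  fm <- prosody_features(list(seg), w)
  expect_equal(dim(fm$values), c(1L, 13L))
  expect_equal(unname(fm$values[1, 2:7]), coefs, tolerance = 1e-6)
})

test_that("prosody: duration arithmetic and constant energy contour", {
  w <- make_tone(120, dur = 1)
  c <- estimate_f0(w)
  segs <- voiced_segments(c, w)
  seg <- segs[[1]]
  seg$end_sample <- seg$start_sample + 9600
  seg$duration <- 9600 / 16000
  seg$f0_track <- seg$f0_track[seq_len(55)]
  fm <- prosody_features(list(seg), w)
  expect_equal(unname(fm$values[1, "duration_s"]), 0.6)
  # constant-amplitude tone: energy polynomial is flat at the node values
  en_coefs <- fm$values[1, 8:13]
  nodes <- seq(0, 1, length.out = 6)
  vals <- drop(outer(nodes, 0:5, "^") %*% en_coefs)
  expect_lt(max(vals) - min(vals), 0.5)   # dB spread across nodes
})

test_that("segments too short for the prosody model are dropped", {
  w <- make_tone(120, dur = 1)
  seg <- structure(list(start_sample = 0, end_sample = 800,
                        start_frame = 0, end_frame = 2,
                        f0_track = c(120, 120, 120), duration = 0.05),
                   class = "voiced_segment")
  fm <- prosody_features(list(seg), w)
  expect_equal(nrow(fm$values), 0L)
  expect_equal(attr(fm, "n_dropped"), 1L)
})
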