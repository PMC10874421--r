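test_that("utterance synthesis is bitwise deterministic given the seed", {
  p <- synth_profile("et", seed = 21)
  w1 <- synth_utterance(p)
  w2 <- synth_utterance(p)
  expect_identical(w1$samples, w2$samples)
})

test_that("each syllable produces exactly one unvoiced-voiced onset", {
  for (ns in c(4L, 7L)) {
    p <- synth_profile("hc", seed = 31, n_syllables = ns)
    w <- preprocess_waveform(synth_utterance(p))
    expect_length(onset_segments(estimate_f0(w), w), ns)
  }
})

test_that("tremor appears at its rate in the F0 modulation spectrum", {
  # sustained nuclei so the modulation spectrum resolves ~0.5 Hz
  p <- synth_profile("et", seed = 41, tremor_rate = 5, tremor_depth = 0.08,
                     n_syllables = 3L, syllable_ms = 2000)
  w <- preprocess_waveform(synth_utterance(p))
  contour <- estimate_f0(w)
  segs <- voiced_segments(contour, w)
  seg <- segs[[which.max(vapply(segs, `[[`, numeric(1), "duration"))]]
  f0 <- seg$f0_track                     # sampled at 1/hop = 100 Hz
  spec <- stats::spec.pgram(f0 - mean(f0), taper = 0, plot = FALSE)
  peak_hz <- spec$freq[which.max(spec$spec)] * 100
  expect_lt(abs(peak_hz - 5), 0.5)
})

test_that("hypokinetic onsets rise more slowly than neutral ones", {
  rise_frac <- function(cls) {
    p <- synth_profile(cls, seed = 51, n_syllables = 5L)
    w <- preprocess_waveform(synth_utterance(p))
    on <- onset_segments(estimate_f0(w), w)
    mean(vapply(on, function(s) {
      right <- abs(s$samples[641:1280])
      # energy in the first 20 ms of voicing relative to the last 20 ms
      sum(right[1:320]^2) / (sum(right[321:640]^2) + 1e-12)
    }, numeric(1)))
  }
  expect_lt(rise_frac("pd"), rise_frac("hc"))
})

test_that("cohorts have the declared size, labels, and reproducibility", {
  co <- synth_cohort(4, seed = 5)
  expect_length(co$waveforms, 12)
  expect_equal(unname(table(co$manifest$class)[c("et", "hc", "pd")]),
               rep(4L, 3), ignore_attr = TRUE)
  co2 <- synth_cohort(4, seed = 5)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$waveforms[[1]]$samples, co2$waveforms[[1]]$samples)

  # zero subject-level variance: per-class profile parameters identical
  cz <- synth_cohort(3, seed = 6, subject_sd = 0)
  for (cl in unique(cz$manifest$class)) {
    sub <- cz$manifest[cz$manifest$class == cl,
                       c("base_f0", "f0_range", "jitter_inject")]
    expect_equal(max(apply(sub, 2, function(v) diff(range(v)))), 0)
  }
})

test_that("mixture sampling matches its parameters to Monte Carlo error", {
  m <- gmm(c(0.3, 0.7), matrix(c(-2, 3, 0, 1), 2, 2),
           matrix(c(1, 4, 2, 1), 2, 2))
  X <- sample_gmm(m, 100000, seed = 3)
  comp <- attr(X, "component")
  # component frequencies within 3 binomial SEs
  for (i in 1:2) {
    se <- sqrt(m$weights[i] * (1 - m$weights[i]) / 100000)
    expect_lt(abs(mean(comp == i) - m$weights[i]), 3 * se)
  }
  # per-component sample means within 3 SEs of the component means
  for (i in 1:2) for (d in 1:2) {
    ni <- sum(comp == i)
    se <- sqrt(m$variances[i, d] / ni)
    expect_lt(abs(mean(X[comp == i, d]) - m$means[i, d]), 3 * se)
  }
  expect_identical(sample_gmm(m, 50, seed = 9), sample_gmm(m, 50, seed = 9))
})

test_that("class-conditional features shift in the documented directions", {
  feats_of <- function(cls, seed) {
    p <- synth_profile(cls, seed = seed)
    extract_features(preprocess_waveform(synth_utterance(p)))
  }
  hc <- feats_of("hc", 61); et <- feats_of("et", 61); pd <- feats_of("pd", 61)
  # hyperkinetic: larger F0 excursions in phonation
  expect_gt(mean(et$phonation$values[, "mean_abs_df0"]),
            mean(hc$phonation$values[, "mean_abs_df0"]))
  # hypokinetic: softer onsets depress early high-band articulation energy
  expect_lt(mean(pd$articulation$values[, 1:22]),
            mean(hc$articulation$values[, 1:22]))
})

test_that("widening class separation does not hurt downstream accuracy", {
  acc_at <- function(s, seed) {
    # at s = 0 the three classes share the neutral profile; at s = 1 they
    # sit at their full presets
    profiles <- list(
      hc = synth_profile("hc", seed = 1),
      pd = synth_profile("pd", base_f0 = 125 - s * 5,
                         f0_range = 30 - s * 22,
                         onset_rise_time = 15 + s * 50,
                         jitter_inject = 0.5 + s * 1.0, seed = 1),
      et = synth_profile("et", base_f0 = 125 + s * 5,
                         f0_range = 30 + s * 10,
                         tremor_depth = 0.08 * s,
                         amplitude_mod_depth = 0.02 + 0.13 * s,
                         jitter_inject = 0.5 + s * 2.0, seed = 1))
    co <- synth_cohort(8, profiles, seed = seed)
    feats <- run_extract(co)
    ubms <- run_train_ubm(feats, co$manifest, m_grid = 2L, seed = 3)
    sv <- suppressWarnings(
      run_adapt(feats, lapply(ubms, function(u) u[["2"]])))
    y <- stats::setNames(factor(co$manifest$class), co$manifest$subject_id)
    r <- run_experiment(sv$fusion, y[rownames(sv$fusion)],
                        experiment_spec(folds = 4, repetitions = 2,
                                        c_grid = c(0.1, 1, 10, 100),
                                        gamma_grid = c(1e-3, 1e-2, 1e-1),
                                        seed = 17))
    r$accuracy_mean
  }
  accs <- vapply(c(0, 0.5, 1), acc_at, numeric(1), seed = 23)
  expect_true(all(diff(accs) >= -1e-9))
  expect_lt(accs[1], 70)     # identical profiles: near chance
  expect_gt(accs[3], 75)     # full separation: high accuracy at this scale
})
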