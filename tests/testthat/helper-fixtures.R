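# shared fixtures, built once per test session

.fixtures <- new.env(parent = emptyenv())

# harmonic tone with unit peak; resembles a sustained vowel
make_tone <- function(f0 = 120, dur = 1, sr = 16000, n_harmonics = 8,
                      source_id = "tone") {
  t <- seq_len(round(dur * sr)) / sr
  x <- rowSums(vapply(seq_len(n_harmonics),
                      function(h) sin(2 * pi * f0 * h * t) / h,
                      numeric(length(t))))
  waveform(x / max(abs(x)), sr, source_id)
}

make_noise <- function(dur = 1, sr = 16000, seed = 1, source_id = "noise") {
  set.seed(seed)
  x <- stats::rnorm(round(dur * sr))
  waveform(x / max(abs(x)), sr, source_id)
}

# signal built from whole sine cycles with prescribed per-cycle periods
# (samples) and peak amplitudes: the ground truth for perturbation tests
make_cycle_signal <- function(periods, amplitudes = rep(1, length(periods)),
                              sr = 16000) {
  x <- unlist(lapply(seq_along(periods), function(k) {
    p <- periods[k]
    amplitudes[k] * sin(2 * pi * (seq_len(p) - 1) / p)
  }))
  waveform(x / max(abs(x)), sr, "cycles")
}

# hand-built F0 contour on the standard 40 ms / 10 ms grid
fake_contour <- function(f0, frame_len = 640, hop = 160, sr = 16000,
                         n_samples = (length(f0) - 1) * hop + frame_len) {
  structure(list(
    frame_times = ((seq_along(f0) - 1) * hop + frame_len / 2) / sr,
    f0 = as.numeric(f0), strength = as.numeric(f0 > 0),
    frame_len = frame_len, hop = hop, sample_rate = sr,
    n_samples = n_samples), class = "f0_contour")
}

# a random small GMM for oracle tests
random_gmm <- function(m, d, seed) {
  set.seed(seed)
  w <- stats::runif(m) + 0.2
  gmm(w / sum(w),
      matrix(stats::rnorm(m * d, sd = 3), m, d),
      matrix(stats::runif(m * d, 0.5, 2), m, d))
}

# the full synthetic study cohort: supervectors at M = 4 adapted from
# HC-trained UBMs; computed once and reused by the end-to-end tests
study_supervectors <- function() {
  if (!is.null(.fixtures$study)) return(.fixtures$study)
  cohort <- synth_cohort(50, seed = 20260901)
  feats <- run_extract(cohort)
  ubms <- run_train_ubm(feats, cohort$manifest, m_grid = 4L,
                        ubm_classes = "hc", seed = 11)
  sv <- suppressWarnings(
    run_adapt(feats, lapply(ubms, function(u) u[["4"]])))
  labels <- stats::setNames(factor(cohort$manifest$class),
                            cohort$manifest$subject_id)
  .fixtures$study <- list(sv = sv, labels = labels[rownames(sv$fusion)],
                          manifest = cohort$manifest)
  .fixtures$study
}
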