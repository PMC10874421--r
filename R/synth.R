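# deterministic 31-bit sub-seed derivation, safe for set.seed()
.derive_seed <- function(master, k = 0) {
  as.integer((as.numeric(master) * 69069 + as.numeric(k) * 1013 + 1) %%
               2147483647)
}

#' Synthetic speaker profile
#'
#' Parameter set for the synthetic utterance generator. The presets emulate
#' the phenomenology of the three cohorts: `"hc"` (neutral voice), `"pd"`
#' (hypokinetic profile: reduced F0 variability, soft/slow voicing onsets),
#' and `"et"` (hyperkinetic profile: 4-8 Hz tremor-like modulation of F0 and
#' amplitude, larger pitch fluctuation).
#'
#' @param class_tag `"hc"`, `"pd"`, or `"et"`; selects preset defaults.
#' @param base_f0 mean fundamental frequency, Hz.
#' @param f0_range slow F0 drift range across syllables, Hz.
#' @param tremor_rate tremor modulation rate, Hz (4-8 for `"et"`, else 0).
#' @param tremor_depth F0 tremor depth as a fraction of `base_f0`.
#' @param amplitude_mod_depth amplitude tremor depth (fraction).
#' @param onset_rise_time voicing onset rise time, ms (long = soft onset).
#' @param jitter_inject cycle-level period perturbation, percent.
#' @param n_syllables number of consonant-vowel syllables (default 21,
#'   seven /pa-ta-ka/-like triplets).
#' @param syllable_ms voiced nucleus duration, ms.
#' @param burst_ms unvoiced burst duration, ms.
#' @param gap_ms silent gap duration, ms.
#' @param seed integer seed; the generator is deterministic given it.
#' @return an object of class `synth_profile`.
#' @export
synth_profile <- function(class_tag = c("hc", "pd", "et"),
                          base_f0 = NULL, f0_range = NULL,
                          tremor_rate = NULL, tremor_depth = NULL,
                          amplitude_mod_depth = NULL,
                          onset_rise_time = NULL, jitter_inject = NULL,
                          n_syllables = 21L, syllable_ms = 220,
                          burst_ms = 80, gap_ms = 60, seed = 1L) {
  class_tag <- match.arg(class_tag)
  preset <- switch(class_tag,
    hc = list(base_f0 = 125, f0_range = 30, tremor_rate = 0,
              tremor_depth = 0, amplitude_mod_depth = 0.02,
              onset_rise_time = 15, jitter_inject = 0.5),
    pd = list(base_f0 = 120, f0_range = 8, tremor_rate = 0,
              tremor_depth = 0, amplitude_mod_depth = 0.02,
              onset_rise_time = 65, jitter_inject = 1.5),
    et = list(base_f0 = 130, f0_range = 40, tremor_rate = 5.5,
              tremor_depth = 0.08, amplitude_mod_depth = 0.15,
              onset_rise_time = 15, jitter_inject = 2.5))
  p <- list(class_tag = class_tag,
            base_f0 = base_f0 %||% preset$base_f0,
            f0_range = f0_range %||% preset$f0_range,
            tremor_rate = tremor_rate %||% preset$tremor_rate,
            tremor_depth = tremor_depth %||% preset$tremor_depth,
            amplitude_mod_depth = amplitude_mod_depth %||%
              preset$amplitude_mod_depth,
            onset_rise_time = onset_rise_time %||% preset$onset_rise_time,
            jitter_inject = jitter_inject %||% preset$jitter_inject,
            n_syllables = as.integer(n_syllables),
            syllable_ms = syllable_ms, burst_ms = burst_ms, gap_ms = gap_ms,
            seed = as.integer(seed))
  stopifnot(p$tremor_rate >= 0, p$tremor_depth >= 0, p$tremor_depth <= 0.5,
            p$amplitude_mod_depth >= 0, p$amplitude_mod_depth <= 0.5,
            p$syllable_ms > 0, p$burst_ms > 0, p$gap_ms > 0,
            p$n_syllables >= 1L)
  structure(p, class = "synth_profile")
}

# one harmonic voiced stretch generated cycle by cycle so that cycle-level
# period jitter is exact; each harmonic starts/ends a cycle at zero phase,
# keeping the waveform continuous across cycle joins
.voiced_nucleus <- function(n_samples, f0_of_t, jitter_pct, sr) {
  out <- numeric(n_samples)
  pos <- 0
  while (pos < n_samples) {
    f <- f0_of_t(pos) * (1 + jitter_pct / 100 *
                           max(-2.5, min(2.5, stats::rnorm(1))))
    f <- max(40, f)
    period <- max(8L, round(sr / f))
    len <- min(period, n_samples - pos)
    ph <- 2 * pi * (seq_len(len) - 1L) / period
    n_h <- min(20L, floor(4000 / f))
    cyc <- numeric(len)
    for (h in seq_len(n_h)) cyc <- cyc + sin(h * ph) / h
    out[(pos + 1L):(pos + len)] <- cyc
    pos <- pos + len
  }
  out / max(abs(out))
}

#' Generate one synthetic utterance
#'
#' A /pa-ta-ka/-like sequence alternating silent gaps, unvoiced noise
#' bursts, and harmonic voiced nuclei. The instantaneous F0 is
#' `base_f0 * (1 + tremor_depth * sin(2 pi tremor_rate t))` plus a slow
#' per-syllable drift within `f0_range`; cycle-level period jitter is
#' injected at `jitter_inject` percent; each nucleus is shaped by a
#' raised-cosine attack of `onset_rise_time` ms; the amplitude carries a
#' tremor-rate modulation of depth `amplitude_mod_depth`. Deterministic
#' given `p$seed`.
#'
#' @param p a [synth_profile()].
#' @param source_id identifier for the resulting waveform.
#' @param sr sampling rate in Hz (default 16000).
#' @return a `waveform`.
#' @export
synth_utterance <- function(p, source_id = paste0(p$class_tag, "_1"),
                            sr = 16000) {
  stopifnot(inherits(p, "synth_profile"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(p$seed)

  gap_n <- round(p$gap_ms / 1000 * sr)
  burst_n <- round(p$burst_ms / 1000 * sr)
  nuc_n <- round(p$syllable_ms / 1000 * sr)
  rise_n <- max(2L, round(p$onset_rise_time / 1000 * sr))
  fall_n <- max(2L, round(0.020 * sr))

  # slow drift: per-syllable F0 targets random-walking inside +/- f0_range/2
  drift <- numeric(p$n_syllables)
  for (s in seq_len(p$n_syllables)[-1L])
    drift[s] <- max(-1, min(1, drift[s - 1L] + stats::rnorm(1, 0, 0.35)))
  f0_syl <- p$base_f0 + drift * p$f0_range / 2

  pieces <- vector("list", p$n_syllables)
  t_offset <- 0
  for (s in seq_len(p$n_syllables)) {
    gap <- numeric(gap_n)
    burst <- diff(c(0, stats::rnorm(burst_n)))          # high-tilted noise
    burst <- burst / max(abs(burst)) * 0.30
    b_env <- c(seq(0, 1, length.out = round(burst_n * 0.2)),
               rep(1, burst_n - 2L * round(burst_n * 0.2)),
               seq(1, 0.3, length.out = round(burst_n * 0.2)))
    burst <- burst * b_env[seq_len(burst_n)]

    nuc_start_t <- t_offset + (gap_n + burst_n) / sr
    f0_of_t <- function(pos) {
      t_abs <- nuc_start_t + pos / sr
      f0_syl[s] * (1 + p$tremor_depth *
                     sin(2 * pi * p$tremor_rate * t_abs))
    }
    nuc <- .voiced_nucleus(nuc_n, f0_of_t, p$jitter_inject, sr)
    env <- rep(1, nuc_n)
    ra <- min(rise_n, nuc_n)
    env[seq_len(ra)] <- 0.5 - 0.5 * cos(pi * (seq_len(ra) - 1L) / (ra - 1L))
    fa <- min(fall_n, nuc_n)
    env[(nuc_n - fa + 1L):nuc_n] <-
      env[(nuc_n - fa + 1L):nuc_n] *
      (0.5 + 0.5 * cos(pi * (seq_len(fa) - 1L) / (fa - 1L)))
    if (p$amplitude_mod_depth > 0 && p$tremor_rate > 0) {
      t_abs <- nuc_start_t + (seq_len(nuc_n) - 1L) / sr
      env <- env * (1 + p$amplitude_mod_depth *
                      sin(2 * pi * p$tremor_rate * t_abs))
    }
    pieces[[s]] <- c(gap, burst, nuc * env)
    t_offset <- t_offset + (gap_n + burst_n + nuc_n) / sr
  }
  x <- c(unlist(pieces), numeric(gap_n))
  x <- x / max(abs(x))
  waveform(x, sr, source_id)
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_per_class` speakers per class around the given profile
#' templates, with subject-level Gaussian random effects on the log scale of
#' the positive profile parameters (so classes overlap realistically), and
#' synthesizes one utterance per speaker. Reproducible from `seed`.
#'
#' @param n_per_class speakers per class.
#' @param profiles named list of `synth_profile` templates (default: the
#'   `hc`, `pd`, `et` presets).
#' @param seed master seed.
#' @param subject_sd standard deviation of the log-scale subject random
#'   effects (default 0.10).
#' @return list with `waveforms` (list of `waveform`s) and `manifest`
#'   (data frame: `subject_id`, `class`, `seed`, and the per-subject profile
#'   parameters).
#' @export
synth_cohort <- function(n_per_class = 50L,
                         profiles = list(hc = synth_profile("hc"),
                                         pd = synth_profile("pd"),
                                         et = synth_profile("et")),
                         seed = 1L, subject_sd = 0.10) {
  waves <- list(); rows <- list()
  idx <- 0L
  for (cl in names(profiles)) {
    tmpl <- profiles[[cl]]
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      sseed <- .derive_seed(seed, idx)
      old <- .save_rng()
      set.seed(sseed)
      jitter <- function(v) v * exp(stats::rnorm(1, 0, subject_sd))
      p <- synth_profile(
        tmpl$class_tag,
        base_f0 = jitter(tmpl$base_f0),
        f0_range = jitter(tmpl$f0_range),
        tremor_rate = if (tmpl$tremor_rate > 0)
          min(8, max(4, jitter(tmpl$tremor_rate))) else 0,
        tremor_depth = min(0.5, jitter(tmpl$tremor_depth)),
        amplitude_mod_depth = min(0.5, jitter(tmpl$amplitude_mod_depth)),
        onset_rise_time = jitter(tmpl$onset_rise_time),
        jitter_inject = jitter(tmpl$jitter_inject),
        n_syllables = tmpl$n_syllables, syllable_ms = tmpl$syllable_ms,
        burst_ms = tmpl$burst_ms, gap_ms = tmpl$gap_ms,
        seed = .derive_seed(sseed, 7L))
      .restore_rng(old)
      sid <- sprintf("%s_%03d", cl, j)
      waves[[sid]] <- synth_utterance(p, source_id = sid)
      rows[[idx]] <- data.frame(
        subject_id = sid, class = cl, seed = p$seed,
        base_f0 = p$base_f0, f0_range = p$f0_range,
        tremor_rate = p$tremor_rate, tremor_depth = p$tremor_depth,
        amplitude_mod_depth = p$amplitude_mod_depth,
        onset_rise_time = p$onset_rise_time,
        jitter_inject = p$jitter_inject, stringsAsFactors = FALSE)
    }
  }
  list(waveforms = waves, manifest = do.call(rbind, rows))
}

#' Draw i.i.d. samples from a Gaussian mixture
#'
#' Oracle sampler used to exercise the GMM and adaptation machinery:
#' components are drawn from the mixture weights, then frames from the
#' per-component diagonal Gaussians. The component of each row is kept in
#' attribute `"component"`.
#'
#' @param model a `gmm`.
#' @param t_len number of frames to draw.
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @return `t_len x D` numeric matrix with attribute `"component"`.
#' @export
sample_gmm <- function(model, t_len, seed = NULL) {
  stopifnot(inherits(model, "gmm"), t_len >= 1)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  comp <- sample.int(model$M, t_len, replace = TRUE, prob = model$weights)
  noise <- matrix(stats::rnorm(t_len * model$D), t_len, model$D)
  x <- model$means[comp, , drop = FALSE] +
    noise * sqrt(model$variances[comp, , drop = FALSE])
  attr(x, "component") <- comp
  x
}
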