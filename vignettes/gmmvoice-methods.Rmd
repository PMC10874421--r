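---
title: "Modelling dysarthric speech with GMM-UBM supervectors"
author: "gmmvoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dysarthric speech with GMM-UBM supervectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Parkinson's disease (PD) and essential tremor (ET) both affect speech, but
differently: PD produces *hypokinetic* dysarthria — monotone pitch, reduced
loudness variation, and a sluggish start of vocal-fold vibration after
unvoiced sounds — while ET produces *hyperkinetic* dysarthria, dominated by
a 4–8 Hz tremor that modulates both pitch and loudness. `gmmvoice`
implements a complete pipeline for turning a raw speech recording into a
fixed-length *supervector* that summarizes these deficits in three speech
dimensions (articulation, phonation, prosody), and for classifying cohorts
of such supervectors with support vector machines under a repeated,
stratified, fully nested cross-validation protocol.

Because clinical recordings of PD/ET cohorts are access-restricted, the
package ships a synthetic-speech generator that produces utterances with the
statistical structure the pipeline assumes. All tests, and the worked
examples in the README, run on that generator.

## Signal preprocessing and segmentation

Every recording is DC-removed, peak-normalized to 1, and resampled to
16 kHz (polyphase rational resampling). Preprocessing is idempotent, and an
all-zero signal passes through flagged rather than causing a division by
zero.

F0 is tracked by a Praat-style autocorrelation method: 40 ms Hann-windowed
frames every 10 ms; the frame autocorrelation (computed by FFT) is divided
by the window autocorrelation to undo the taper bias, candidate peaks are
restricted to 60–400 Hz (bracketing adult speech), and the winning peak is
refined by parabolic interpolation. Three thresholds matter:

* `voicing_threshold` (default 0.45) — minimum normalized peak strength for
  a voiced decision;
* `octave_cost` (default 0.10 per octave of lag) — penalizes subharmonic
  candidates whose peaks tie with the true period, preventing octave drops;
* `silence_threshold` (default 0.03) — frames quieter than 3 % of the
  loudest frame RMS are unvoiced.

The contour is then cleaned: an isolated voiced frame between unvoiced
neighbours is treated as spurious and dropped, and a single-frame voicing
dropout inside a voiced run is filled with the mean of its neighbours. This
mirrors the path-smoothing of practical pitch trackers and keeps the
segmentation aligned with what a human would call a voiced stretch.

Voiced segments are maximal runs of voiced frames (minimum duration 40 ms,
the length of one analysis frame), mapped to 0-based half-open sample
intervals. Onset segments take 40 ms of signal to each side of every
unvoiced-to-voiced border (80 ms, 1280 samples at 16 kHz); borders within
40 ms of a signal edge are dropped rather than zero-padded, because padding
would inject silence into the band energies. Offsets (voiced-to-unvoiced)
are deliberately not extracted.

## Acoustic features

**Articulation (58 per frame).** Each onset segment is analysed in 40 ms
frames shifted by 20 ms (three frames per segment): 22 critical-band log
energies on Traunmüller's Bark scale spanning 0–8 kHz (log floor `1e-10`),
plus 12 MFCCs (26 triangular mel filters, DCT-II, coefficients 1–12, c0
excluded) with first and second temporal derivatives (central differences
with edge replication, computed within the segment). Column order is
`[22 Bark | 12 MFCC | 12 dMFCC | 12 ddMFCC]`.

**Phonation (7 per voiced segment).** Glottal cycle marks are placed at
rising zero crossings of the mean-removed signal, guided by the local F0
estimate (candidate crossings must sit 0.6–1.5 expected periods after the
previous mark; unreachable stretches break the mark train rather than
corrupting the period sequence). From the resulting period and peak
amplitude sequences: jitter (mean absolute consecutive period difference
over mean period, %), shimmer (amplitude analogue), the 5-point period
perturbation quotient PPQ and the 11-point amplitude quotient APQ (segments
with 5–10 cycles use all available cycles as the neighbourhood; fewer than
5 cycles drops the segment from phonation only), the mean absolute first
and second frame-to-frame F0 differences (Hz), and the segment log energy
(dB). One row per voiced segment, so that phonation, like prosody, yields a
fixed-width per-segment observation.

**Prosody (13 per voiced segment).** Segment duration (s), six coefficients
of a degree-5 polynomial modelling the F0 contour over normalized time
(exact interpolation at 6 frames, least squares beyond), and six
coefficients of the degree-5 Lagrange polynomial through the frame energy
contour (dB) evaluated at 6 equally spaced nodes. F0 is kept in Hz; a
semitone scale would equalize variance across speakers with different
baseline pitch and is a known limitation of this feature set.

Jitter, shimmer, APQ and PPQ are ratios and therefore invariant to
amplitude scaling; all features are invariant to time shifts by whole hop
multiples (prepending silence moves timestamps, not values).

## The GMM-UBM model

Frames of each speech dimension are modelled by a diagonal-covariance
Gaussian mixture, the *universal background model* (UBM), fit by EM:

* initialization: k-means++-seeded k-means on a subsample (cap 5000
  frames), seeded and reproducible;
* variance floor: `1e-4` of each dimension's data variance, preventing
  singular components on small segments;
* convergence: relative change of the mean log-likelihood below `1e-5`, or
  200 iterations; the likelihood trace is stored and is non-decreasing;
* a component collapsing to zero soft count is re-seeded at the frame with
  the lowest current log-density.

By default the UBM is trained on the healthy-control cohort only, exposed
as configuration (`ubm_classes`), since patient-inclusive background models
are a legitimate alternative.

Each recording is then adapted to the UBM by a single maximum a posteriori
(MAP) pass. With soft counts `n_i`, first moments `E_i(x)` and second
moments `E_i(x^2)` of the recording's frames under the UBM, and
`alpha_i = n_i / (n_i + r)` with relevance factor `r = 16`:

* weights: `w'_i = [alpha_i n_i / T + (1 - alpha_i) w_i] * gamma`, with
  `gamma` restoring the sum to 1;
* means: `mu'_i = alpha_i E_i(x) + (1 - alpha_i) mu_i`;
* variances: `sigma'^2_i = alpha_i E_i(x^2) +
  (1 - alpha_i)(sigma^2_i + mu^2_i) - mu'^2_i`, floored at the UBM floor.

A single shared `alpha_i` adapts all three parameter groups; components
that saw no data are untouched; a second MAP pass would change the result,
so exactly one pass is performed (classical GMM-UBM practice), keeping
adaptation deterministic. The adapted means and diagonal covariances are
stacked into a supervector of length `2 M D` — e.g. 464 numbers for
articulation at `M = 4`. Early fusion concatenates the three dimensions'
supervectors as `[articulation | phonation | prosody]`.

## Classification and evaluation

Supervectors are classified by an RBF-kernel SVM under stratified 10-fold
cross-validation repeated 10 times. Inside each training fold, strictly in
this order and fit on the training fold only: per-column z-scoring
(population SD; constant columns map to 0), optionally PCA keeping the
smallest number of components reaching 90 % cumulative variance, and a
hyperparameter grid search over
`C ∈ {0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5, 10, 50, 100, 500, 1000}`
and `gamma ∈ {1e-4, …, 1e3}` (the decade/half-decade pattern implied by the
printed endpoints), scored by stratified 5-fold inner cross-validation.
Ties in the grid, and in the modal hyperparameters reported across folds
and repetitions, break toward smaller `C`, then smaller `gamma` — simpler
models. Three-class problems use one-vs-rest classifiers with arg-max over
decision values; sensitivity and specificity are macro-averaged one-vs-rest
in that case, and PD-positive in the two-class case. Accuracy is reported
as mean ± SD **over repetitions** (never over folds); the confusion matrix
is pooled over folds and averaged over repetitions, so its row sums equal
the class counts.

Nested selection was a deliberate design choice: selecting `M` or
`(C, gamma)` on the same folds that produce the reported accuracy would
bias it upward. `M` is selected by an outer sweep over
`{2, 4, 8, 16, 32, 64, 128}`, reporting the best row per configuration.

One engineering note: the nested protocol needs on the order of 10^5 SVM
fits per experiment. The inner grid is therefore scored by a compact
second-order SMO solver (C++, precomputed squared-distance matrix, one
kernel evaluation per `gamma`, warm starts along the ascending `C` path),
while the model actually fit and evaluated in every outer fold comes from
`e1071::svm` (libsvm). The test suite pins the two solvers against each
other across the grid; decision values agree to well below the score scale.

All randomness (fold draws, initialization) derives from one master seed
through a deterministic sub-seed chain, so identical configurations yield
byte-identical result tables.

## The synthetic cohort

The generator is source-filter-lite: harmonic voiced nuclei (additive
harmonics with 1/h roll-off, built cycle by cycle so that cycle-level
period jitter is exact) alternating with high-tilted noise bursts and
silent gaps — a /pa-ta-ka/-like syllable train. Defaults were chosen once
to mirror the diadochokinetic task conditions: 21 syllables (seven
/pa-ta-ka/ triplets in one breath), 220 ms nuclei, 80 ms bursts, 60 ms
gaps, about 7.5 s per utterance; cohorts of 50 speakers per class (HC, PD,
ET) with log-normal subject-level random effects (SD 0.10) on all positive
profile parameters.

Class profiles encode the clinical phenomenology: the ET-like profile adds
5.5 Hz tremor (depth 0.08 on F0, 0.15 on amplitude) and raised cycle jitter
(2.5 %); the PD-like profile narrows the slow F0 drift range to 8 Hz and
lengthens the voicing onset rise to 65 ms (soft onsets) with jitter 1.5 %;
the neutral profile sits at 30 Hz drift, 15 ms onsets, 0.5 % jitter. These
separations are intentionally strong: the synthetic study verifies the
pipeline's mechanics (segmentation counts, dimension contracts, fusion not
losing information, chance-level behaviour under label permutation), not
clinical effect sizes. What the generator does **not** emulate — vocal
tract resonances, phonotactics, channel/microphone variation, comorbid
voice pathology — is exactly what makes real corpora harder, so passing
tests here bound correctness, not clinical performance.

## Problem sizes used by the test suite

The shipped tests run the full study at 150 subjects with the complete
grids and the 10×10-fold protocol for the tri-class experiments, and
scaled-down cohorts (8–12 subjects per class, reduced grids, 2
repetitions) for property checks such as separation monotonicity and
byte-level reproducibility of pipeline outputs; EM parameter recovery is
checked at T = 20 000 frames. These sizes are the package's choice of a
thorough-but-routine regression suite.

## Known limitations

* F0 stays in Hz; no semitone normalization.
* One MAP pass with a single shared relevance factor; no eigenvoice or
  channel compensation.
* The F0 tracker is a single-pass autocorrelation method with local
  smoothing, not a Viterbi path search; creaky or diplophonic voicing
  would need the latter.
* Phonation log-energy is per segment (one row per voiced segment); a
  per-frame variant would change the phonation row count but not its
  width.
* The generator's classes are separable by construction; accuracy numbers
  on it say nothing about clinical discriminability.
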