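---
title: "Methods: skin-conductance drowsiness detection in scdrowse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skin-conductance drowsiness detection in scdrowse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdrowse)
```

## The problem

Electrodermal activity — skin conductance (SC), in microsiemens — rises
with sympathetic arousal and falls as a driver becomes drowsy, which makes
it attractive for non-intrusive drowsiness monitoring from a wrist-worn
device. Two obstacles stand between a wrist SC stream and a usable
drowsiness label. First, wrist recordings are contaminated by motion
artifacts: electrode-contact changes during wrist movement produce abrupt
excursions easily mistaken for genuine skin conductance responses (SCRs).
Second, the physiologically meaningful structure lives in two superimposed
components — a slowly drifting tonic level (SCL) and fast event-related
phasic responses (SCRs) — that must be separated before features are
computed. `scdrowse` implements the full chain: accelerometer-gated
wavelet artifact removal, tonic/phasic decomposition, windowed feature
extraction with redundancy pruning, and cross-validated ensemble
classification against Karolinska Sleepiness Scale (KSS) self-reports.

## Artifact removal

The filter operates segment-wise on the stationary (undecimated) Haar
wavelet transform (SWT). For each segment, every detail level `d_j` is
thresholded with the Laplace rule

    T_low = mean(|d_j|) * ln(delta),    T_high = -T_low,

where `delta` is the assumed proportion of artifact-corrupted samples: if
the clean-signal coefficients are zero-mean Laplace with scale `b`, then
`mean(|d_j|)` estimates `b` and exactly a fraction `delta` of coefficients
falls outside `[T_low, T_high]`. Coefficients outside the band are treated
as artifacts and set to zero (the replacement value is a design choice;
zeroing is the hard-thresholding convention), and the segment is rebuilt
with the inverse transform. The approximation band is never modified.

`delta` is set per segment from the wrist accelerometer: when the sample
standard deviation of **every** axis over the segment's time span stays
below 0.04 m/s² the segment is presumed quiet (`delta = 0.01`); if any
axis exceeds the gate, motion is assumed and `delta = 0.10` widens the
artifact fraction tenfold. Acceleration is aligned by timestamp, never
resampled.

The decomposition depth is tied to the sampling rate by
`j = log2(fs) + 2` (4 levels at 4 Hz, 10 at 256 Hz), exposed as
`decomposition_level()`. The filter itself also accepts an explicit `j`:
the joint-artifact analyses below use `j = 7` (128-sample segments), the
configuration under which the boundary phenomenon is classically shown,
and gating analyses use the rule's value. The two conventions coexist in
the literature this design follows; the package does not reconcile them,
it parameterises them.

### Why two variants

**Original:** non-overlapped segments of `2^j` samples. The SWT here uses
periodic boundary handling, so a drifting signal acquires an artificial
jump at each segment boundary; the jump produces large detail
coefficients, the Laplace rule removes them, and the reconstruction
develops spikes at the joints — visible every `2^j` samples and large
enough (often > 0.01 μS) to corrupt the SCR peak count, one of the most
used EDA features.

**Improved:** segments of `2 * 2^j` samples sliding with hop `2^j`; only
the central `2^j` samples of each reconstruction are kept, so the
boundary-localised damage falls in discarded margins and the retained
parts tile the output exactly. Signal ends are reflection-padded by
`2^(j-1)` samples. The overlap description in the source material is
ambiguous ("overlapping window equal to `(2^j)/2`"); the hop-`2^j`,
central-retention geometry was chosen because it tiles without gaps and
needs no blending. `compare_filters()` quantifies the difference — on an
artifact-free signal the improved variant is numerically indistinguishable
from its input while the original variant's deviations concentrate within
a couple of samples of the joints.

### A scale caveat

The "no difference on clean signal" property belongs to the benchtop
sample density. At 256 Hz a 128-sample segment spans 0.5 s, over which SC
is smooth and its coefficients homogeneous: with `delta = 0.01` nothing
crosses `4.6 * mean(|d|)` and the filter is the identity. At the raw 4 Hz
a 128-sample segment spans 32 s and contains entire SCR transients, whose
coefficients *are* segment-scale outliers; the rule then clips genuine
SCRs in either variant. This is an inherent property of
segment-relative thresholding, and one more reason the processing chain
interpolates to 256 Hz *before* filtering (see below).

## Oversampling

Wrist devices sample SC at 4 Hz; benchtop physiological DAQs at 256 Hz.
`oversample_linear()` raises the wrist stream to the benchtop grid by
linear interpolation between neighbouring samples, reproducing the
original instants exactly. Interpolation precedes artifact removal in
`run_pipeline()`; the output spans the same interval, so a 4 Hz signal of
`n` samples becomes `(n - 1) * 64 + 1` samples at 256 Hz (one fewer
15-second window than the 4 Hz stream, whose last window the interpolated
grid cannot complete).

## Tonic/phasic decomposition

The split method is deliberately simple and exactly additive: SCL is a
zero-phase (forward-backward) first-order Butterworth low-pass at
0.05 Hz — the conventional tonic cutoff — and SCR is the residual, so
`sc = scl + scr` holds to machine precision. Forward-backward filtering
is applied over an odd-reflection-padded copy of the signal
(pad `3 * fs / cutoff` samples each side) because the underlying filter
implementation starts from zero state and would otherwise leak a large
startup transient into the tonic estimate. Cutoff and order are exposed;
any split summing to the original satisfies downstream contracts, but
feature values of course depend on the choice. Model-based deconvolution
of the SCR driver is out of scope.

## Windows, labels, features

Signals are cut into consecutive non-overlapping 15-s windows (60 samples
at 4 Hz); a trailing partial window is dropped with a message. Each window
takes the KSS score of the reporting interval covering its start: a score
reported at time `t` covers `[t - 600 s, t]`, and a window starting
exactly on a shared boundary joins the earlier interval. Scores collapse
to three classes: 1–5 alert, 6–7 slightly drowsy, 8–9 drowsy.

Per window, 23 features are computed: nine moment statistics of the SC
samples (mean, sd, min, max, median, kurtosis, skewness, variance, range),
the same nine of the one-sided FFT magnitude spectrum (scaled by `1/fs`,
DC included; "median" etc. are statistics of the magnitude values, not of
frequencies), the count of SCR local maxima above the 0.01 μS relevance
threshold, and four SCL statistics (mean, sd, min, max). Skewness and
kurtosis are the plain third and fourth standardised moments (no excess
correction), defined as 0 on zero-variance windows; sd and variance use
the `n - 1` denominator.

Redundant features are pruned greedily in canonical catalogue order: a
feature is dropped when its absolute Pearson correlation with any
already-retained feature exceeds 0.90. The five features that are
near-duplicates of retained ones on typical data — SC mean, SC max, SC
median, SCL mean, SCL max — are listed last in the catalogue, so the
greedy pass discards exactly those five (leaving 18) whenever the
collinearity is present. A feature-vs-class correlation ranking
(`feature_class_correlation()`), the quantity WEKA-style attribute
evaluators report, is provided separately; pruning is deliberately
feature-vs-feature because the named discarded set is characteristic of
inter-feature redundancy and this reproduces it deterministically.

## Classification

Three ensembles over the selected features: random forest, bagging
(implemented as a forest that considers every predictor at each split,
the canonical reduction of bagged trees), and boosting (multi-class
adaptive boosting, SAMME, over CART trees of depth ≤ 3, 50 rounds —
the named method is generic "Boosting", so the standard multi-class
AdaBoost family was chosen; rounds and depth are exposed). Evaluation is
stratified 10-fold cross-validation, seeded; pooled out-of-fold
predictions form one confusion matrix. Per class, one-vs-rest TP/TN/FP/FN
give accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)` and recall
`TP/(TP+FN)` as percentages to one decimal; aggregate accuracy is
trace/total (identical to micro-averaged one-vs-rest accuracy), and
aggregate precision/recall are support-weighted by default (macro by
flag). Windows are pooled across the session; subject-wise grouping is a
question the package leaves to the caller by evaluating whatever table it
is given. Hyperparameters (100 trees, 50 boosting rounds) are defaults,
not tuned values.

## The synthetic session generator

No recorded sessions ship with the package; `generate_session()` produces
sessions with exactly the statistical structure the pipeline assumes, plus
ground truth for every injected element. Defaults describe a 40-minute
drive with KSS reports every 10 minutes and a latent drowsiness state per
10-minute block (default profile 1, 1, 2, 3 — a driver gradually becoming
drowsy):

* **Tonic:** base 2 μS with state-dependent drift 0 / −0.02 / −0.04 μS
  per minute for states 1/2/3 — tonic level declines as arousal falls;
  magnitudes are small against the base, as in multi-minute wrist
  recordings.
* **Phasic:** Poisson SCR events at 6 / 3 / 1 events per minute for
  states 1/2/3 (spontaneous SCR rates fall with drowsiness), amplitudes
  uniform on 0.02–0.2 μS, shaped by a causal unit-peak bi-exponential
  kernel with rise 0.75 s and decay 2 s — standard EDA phenomenology;
  the closed-form peak location `ln(τd/τr)·τr·τd/(τd−τr)` anchors its
  tests.
* **Noise:** additive Gaussian, sd 0.005 μS, so clean SCR peaks
  (≥ 0.02 μS) stay above the 0.01 μS relevance threshold.
* **Artifacts:** bursts at 0.5/min, 2 s long, ±0.5 μS spiky excursions,
  with epochs snapped to the SC sample grid. The triaxial acceleration is
  0.01 m/s² Gaussian wobble per axis outside bursts (safely below the
  0.04 gate) and 0.5 m/s² shaking inside. Snapping epochs to the SC grid
  guarantees that any epoch–segment overlap contributes at least one SC
  sample's worth (≥ 8 acceleration samples at 32 Hz) of shaking, so the
  σ-gate flags exactly the overlapping segments for every seed rather
  than for lucky ones.
* **KSS:** scores drawn from the latent state's band (1→1..5, 2→6..7,
  3→8..9), so grouping the scores recovers the state sequence exactly.

What the generator does **not** emulate: temperature/humidity effects,
electrode drift and polarisation, inter-subject variability, respiration
coupling, or any dependence of artifact shape on movement type. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
that its stages compose as designed — not that the reported synthetic
classification accuracies transfer to human recordings. Synthetic classes
are separable by construction (rates and drifts differ across states);
real KSS classes are far noisier.

## Numerical choices and conventions

* SWT: orthonormal Haar pair, periodic boundaries, à-trous filter
  upsampling; inverse averages the two shift-consistent branch
  reconstructions per level (exact; round-trip error < 1e-9, checked
  against a brute-force convolution oracle).
* Segment tails shorter than one segment are reflection-padded, filtered,
  truncated — output length always equals input length.
* `fs` not a power of two: `round(log2 fs)` with a warning.
* SCR peaks are *strict* local maxima above threshold; plateau samples do
  not count.
* Zero-variance windows: skewness = kurtosis = 0 by convention.
* Constant feature columns are dropped at pruning with a warning
  (correlation undefined).
* A class with fewer members than folds triggers a non-stratified split
  with a warning; a class with no true instances is excluded from
  aggregate metrics with a warning.
* Determinism: every stochastic step (generator, fold assignment, model
  fitting) runs under `withr::with_seed` from an explicit seed argument.

## Problem sizes

The shipped tests run on 10- and 40-minute synthetic sessions (2 400 to
9 600 SC samples at 4 Hz; 614 337 samples where the 256 Hz density is
exercised), feature tables of 160–180 windows, and 10-fold
cross-validation with 100-tree forests — sizes chosen so the whole suite
completes in well under a minute on a laptop core while every statistical
check retains comfortable margins (e.g. Poisson 3σ bands on SCR counts,
binomial 3σ bands on permutation-null accuracy).

## Known limitations

* Only the Haar mother wavelet is implemented; the thresholding machinery
  is wavelet-agnostic but no other filter pair is wired in.
* The Laplace rule clips genuine SCRs at low sample densities (see the
  scale caveat); the pipeline mitigates this by interpolating first, but
  a 4 Hz-native run with `j = 7` will distort phasic features.
* Pruning is a greedy single pass: it guarantees the retained set is
  pairwise below threshold, not that it is the maximum such set.
* The KSS covering convention assumes reports arrive at most
  `covers_prior_s` apart; gaps leave windows unlabelled and raise an
  error rather than guessing.
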