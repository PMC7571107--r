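---
title: "Classifying acute stress from inter-beat-interval images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying acute stress from inter-beat-interval images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibistress)
```

## The problem

Acute psychological stress activates the sympathetic nervous system: the
heart beats faster and beat-to-beat variability (HRV) drops. Wrist-worn
photoplethysmography (PPG) devices such as the Empatica E4 export exactly
the signal needed to see this — a sequence of inter-beat intervals (IBIs),
one row per detected heartbeat, with a timestamp and the beat duration in
seconds. `ibistress` turns such labeled IBI sequences (stressed vs
non-stressed, e.g. from a laboratory stress protocol like the TSST) into
small images and classifies them with a deep convolutional network. It
supports the three evaluation settings that matter in practice:

* **person-specific** models, trained and tested on one subject;
* **generic** models, trained on some subjects and tested on three held-out
  subjects — the realistic "unseen user" setting, where accuracy drops
  because stress physiology is individual;
* **calibrated-generic** models, in which 20% of each test subject's images
  are injected into the training pool — a cheap personalization step that
  recovers much of the lost accuracy.

## From beats to images

**Filtering.** Beats outside a physiologic window (default 0.6–1.2 s,
i.e. 50–100 bpm at rest; both bounds configurable) are removed by
`filter_physiologic()`. Nothing else is corrected.

**Binning.** `fit_bins()` divides the IBI range into 28 intervals. The
default method places interior edges at empirical quantiles ("according to
the distribution" of the data), so each row of the image is roughly equally
occupied; equal-width bins are an option. Two deliberate choices:

* the outer edges are anchored to the configured physiologic range, not to
  the sample extremes. In the generic regimes the scheme is fitted on the
  *training* subjects only and applied unchanged to test subjects, and
  range-anchored edges guarantee every filtered test beat is encodable;
* degenerate fits are handled without exceptions: too few distinct values
  falls back to equal-width edges, duplicated quantile edges are
  deduplicated and the widest gaps split until 28 intervals are restored.
  Both events leave a record in the scheme's `warnings` field.

**Encoding.** Each beat becomes a one-hot 28-vector (a 1 in its duration
interval). `make_images()` slides a 28-beat window along the sequence —
default stride 1, i.e. the window moves by one column — and emits one
28×28 binary matrix per position. Row 1 is the shortest-IBI interval;
vertical flipping happens only at PNG export. A strict one-hot image has
exactly 28 nonzero pixels, so its mean intensity is constant
(28·255/784 ≈ 9.1 on the rendered 0–255 scale) regardless of class — the
class signal lives in the *pattern* of occupied rows, not in the mean.
Windows never cross recorded segment boundaries (e.g. the join between a
public-speaking and a mental-arithmetic recording merged by
`merge_stress_segments()`).

**Frequency domain.** `to_frequency_images()` applies, per image: 2-D FFT
→ shift of the zero-frequency component to the matrix center → magnitude →
log10 → min–max normalization of the finite values to [0, 255]. The FFT is
used unnormalized; the 1/(MN) factor of the textbook transform definition
is constant per image and cancels in the normalization (the direct
double-sum implementation `dft2_reference()` keeps the factor and serves as
the oracle in the test suite). Zero-magnitude pixels (log = −∞) render as
0, the darkest value.

Numerical choices worth knowing about:

* magnitudes below 10⁻¹² of the per-image maximum are treated as exact
  zeros before the log. The fast transform leaves O(10⁻¹³) rounding residue
  where the exact spectrum is zero; without the floor, the log scale
  amplifies that noise into spurious dark-pixel structure and breaks the
  centro-symmetry of real-input spectra.
* if, after the log, only a single finite level remains over a zero-energy
  background (a pure-DC image), the finite pixels map to 255; if the whole
  spectrum is one finite constant (no background at all), the image is
  emitted all-zero with a warning record. Neither case raises an error.

## The classifier

`cnn_config()` fixes the topology: 8 convolution layers (3×3 kernels,
size-preserving padding) producing 32, 32, 64, 64, 128, 128, 256, 256
feature maps, a 2×2 max-pool after every second convolution (the 28×28
input shrinks 28 → 14 → 7 → 3 → 1 under floor division), then dense layers
of 256, 256 and 1 units with dropout 0.5 after each hidden dense layer,
ReLU activations, and a sigmoid output giving the probability of
"stressed". Ties at probability 0.5 go to the positive (stressed) class.

Training settings not determined by the architecture are exposed with
standard defaults: Adam with learning rate 10⁻³, binary cross-entropy,
batch size 32, 150 epochs (the generic-model setting; scale down for quick
experiments), He initialization. The implementation is single-precision
im2col + GEMM in compiled code (RcppArmadillo), single-threaded and seeded
end to end — identical seed, data and machine give bit-identical runs.
Frequency-domain images are mapped from [0, 255] to [−0.5, 0.5] before
entering the network: they are mostly bright (the log-magnitude spectrum
of a one-hot image is high almost everywhere), and without centering the
large common input component stalls the first many epochs of optimization
at chance. `predict()` applies the same transform automatically.

## Evaluation regimes

`make_split()` implements the three regimes with floor rounding and the
remainder assigned to training:

* person-specific: stratified-by-class 70/15/15 train/validation/test.
  The default draw is random; with stride-1 windows, random splits place
  near-duplicate windows (sharing up to 27 of 28 beats) on both sides of
  the train/test divide, which inflates person-specific accuracy. A
  `chronological = TRUE` option splits by window position instead, and
  `leakage_report()` quantifies the overlap either way. Both modes are
  provided because the appropriate choice depends on whether one wants to
  reproduce the classical protocol or bound its optimism.
* generic: all images of the named test subjects go to test; the remaining
  subjects' pooled images are split 85/15 (stratified by class) into
  train/validation. The 85/15 proportion is a package default — the
  original protocol does not state how its twelve training subjects were
  divided.
* calibrated-generic: as generic, then exactly `floor(0.2·n)` images per
  test subject per class move from test to training.

`evaluate_predictions()` reports the confusion counts (stressed =
positive) with accuracy, sensitivity, specificity and precision; a zero
denominator yields a flagged `NaN`, never a silent 0. `run_regime()` wires
the whole pipeline (filter → fit bins on the regime-appropriate pool →
encode → split → train → evaluate) and `kfold_cv()` adds stratified k-fold
cross-validation with a pluggable classifier.

## The synthetic cohort generator

WESAD-style datasets cannot ship with a package, so `cohort_spec()` /
`generate_cohort()` simulate the statistical structure the method relies
on:

* stress shortens the mean IBI (defaults 0.70 s vs 0.85 s) and reduces its
  variability (0.04 s vs 0.08 s);
* each subject carries a stable mean-IBI offset drawn once from
  N(0, `subject_shift_sd`²) (default 0.05 s; 0.08 s makes a visibly hard
  generic problem) and shared by both conditions — this is the knob that
  makes generic models degrade on unseen subjects;
* within a sequence, durations follow a stationary AR(1) process. The
  default coefficient is 0.45: the variance of a 28-beat window mean grows
  with (1+φ)/(1−φ), and the generator must keep its core promise that
  window means separate the conditions almost perfectly when subjects are
  homogeneous — at φ = 0.9 that contract would be unattainable at the
  default separation, so smoothness was traded down in its favor;
* durations are clipped (not resampled) to the physiologic range, so range
  filtering is a no-op on clean synthetic data; a `contamination` fraction
  inserts out-of-range artifact beats to exercise the filter.

Everything derives from one integer seed, per subject, so cohorts are
reproducible beat for beat.

What the generator does **not** emulate: respiratory sinus arrhythmia,
circadian drift, motion artifacts, device-specific beat-detection errors,
or any nonstationarity within a condition. Tests passing on this generator
therefore demonstrate that the pipeline recovers a planted
mean/variability class signal under subject heterogeneity — not that any
particular accuracy carries over to field PPG recordings.

## Problem sizes used by the shipped tests

The test suite and `scripts/acceptance.R` run the pipeline at desk scale,
chosen once as the package's own benchmark conditions: person-specific
recovery uses one subject with 1,500 beats per condition and 30 training
epochs (≈2,900 stride-1 windows); the calibration study uses 9 subjects
with 80 beats per condition, subject offset SD 0.08 s, three rotating
test triples, three seeds and 3 epochs per model; the acceptance script
uses 800 and 150 beats per condition with 15 and 6 epochs respectively.
At these sizes the planted signal is comfortably learnable and the
qualitative ordering person-specific > calibrated-generic ≥ generic is
reproducible.

## Known limitations

* Binary classification only (stressed vs non-stressed); no multi-class
  affect states and no stress *prediction* ahead of time.
* No raw-PPG peak detection: the package starts from IBI files.
* The classical random person-specific split measures something closer
  to window memorization than to forecasting, because of stride-1 window
  overlap; use the chronological split for a stricter estimate.
* Training is CPU-bound compiled code; it is fast for 28×28 inputs but not
  a general-purpose deep-learning framework.
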