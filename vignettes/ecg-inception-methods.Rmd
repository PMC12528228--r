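---
title: "Methods: 1D Inception networks, double soft F1-loss, and lead-level explanations for multi-label ECG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 1D Inception networks for multi-label ECG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A resting 12-lead electrocardiogram is a 10-second recording of twelve
voltage traces (leads I, II, III, aVR, aVL, aVF, V1–V6) sampled at a few
hundred hertz. A single recording may carry several simultaneous
diagnostic annotations — atrial fibrillation together with a bundle
branch block, say — which makes automated interpretation a *multi-label*
classification problem. `ecgception` implements a complete desk-scale
pipeline for this problem: record I/O in the WFDB dialect used by the
large public challenge corpora, resampling, a one-dimensional Inception
convolutional network, a differentiable macro-F1 training loss aimed at
heavy class imbalance, stratified cross-validation, and LIME-based
surrogate explanations aggregated into a global condition-by-lead
importance map.

The package is exercised end to end on synthetic corpora produced by its
own generator, so every claim made by the test suite is reproducible
without downloading clinical data.

## Data model and preprocessing

A record is a `12 × n` matrix of millivolt amplitudes plus header
metadata (sampling frequency, age, sex, and diagnosis codes). Headers
follow the challenge convention: a `.hea` text file with `# Age:`,
`# Sex:` and `# Dx:` comment lines, and a sibling `.mat` (MAT v4) file
holding one integer matrix `val` at a gain of 1000 units per millivolt.
Diagnoses are SNOMED-CT codes; the ordered 30-condition catalog with its
code mapping ships as an editable CSV (`extdata/dx_mapping.csv`) and
defines the index of each condition in the 30-bit label vector. Codes
outside the catalog are ignored with a warning, so a record annotated
only with out-of-scope conditions legitimately yields the all-zero
label.

Only 10-second records are admitted (`filter_ten_second()`); the default
tolerance is zero seconds, i.e. the sample count must equal
`round(10 * fs)`. Longer recordings are typically Holter or stress-test
traces with a different measurement protocol and are out of scope.

Resampling (`resample_record()`) is done in the Fourier domain: the
spectrum is truncated or zero-padded to the target length, with the
Nyquist bin folded (downsampling) or split (upsampling) so the inverse
transform is real. This choice is deterministic and anti-aliased for
band-limited content, which matters because the sampling-frequency sweep
is meaningful only if downsampling itself does not inject artifacts.
Amplitudes are not normalized before training; batch normalization in
the first network stage absorbs scale.

## The network

`build_model()` constructs the fixed architecture: symmetric zero-pad of
3, a kernel-7/64-filter convolution, batch norm, ReLU, max-pool (3,
stride 2), a kernel-5/64-filter convolution (same padding), batch norm,
ReLU, two Inception blocks, max-pool (7, stride 2), global average
pooling, and a dense layer with one sigmoid output per condition. Each
Inception block runs four parallel paths on its input — a 1-convolution;
1- then 3-convolution; 1- then 5-convolution; and max-pool (3, stride 1)
then 1-convolution — every convolution followed by batch norm and ReLU,
with outputs concatenated along the feature axis.

Open structural choices were resolved as follows:

* **Path widths.** Only the post-pooling feature width (64) is fixed by
  the architecture; the default split is `(16, 16, 16, 16)`, the
  simplest allocation consistent with it. `model_config()` accepts any
  four positive widths that sum to the stem filter count.
* **Bottleneck widths.** The 1-convolutions opening paths two and three
  use the same filter count as their path output.
* **Padding.** The first stem convolution is a valid convolution after
  the explicit zero-pad layer; all other convolutions use same-padding
  (the Inception paths must stay concatenable). Max-pools use no
  padding; `model_length_trace()` gives the closed-form
  `floor((l + 2p - k)/s) + 1` arithmetic for every stage and is asserted
  against the live network in the tests.
* **Initialisation.** Glorot-uniform, seeded; the same seed rebuilds
  bit-identical weights.

No deep-learning framework is involved: the forward and backward passes
(im2col convolution via BLAS `gemm`, batch-norm, pooling) are implemented
in RcppArmadillo with analytic gradients, verified against central
finite differences through the whole network.

## Losses and metrics

Training minimises either binary cross-entropy or the **double soft
F1-loss**. For class $j$ over a batch, with probabilities $\hat y$ and
labels $y$, the soft counts are
$tp_j=\sum_i \hat y_{ij} y_{ij}$, $fp_j=\sum_i \hat y_{ij}(1-y_{ij})$
and $fn_j=\sum_i (1-\hat y_{ij}) y_{ij}$, and the per-class loss is
$1 - 2tp_j/(2tp_j+fp_j+fn_j+10^{-16})$, averaged unweighted over
classes. The loss is a smooth surrogate of $1-\mathrm{F1}$: it rewards
recall on rare positives symmetrically with precision, which is the
point in corpora where condition prevalences span two orders of
magnitude.

A second form of the false-negative term,
$\sum_i (1-\hat y_{ij})(1-y_{ij})$ — actually a soft *true-negative*
count — circulates in print. Under it a perfect prediction does not
reach zero loss, which contradicts the purpose of a loss function, so
the standard form above is the default; the alternative is available as
`variant = "verbatim"` for fidelity comparisons. Both variants and
their analytic gradients are tested against scalar-loop oracles and
finite differences.

The loss is computed per batch (macro over classes within the batch),
the only aggregation level usable in mini-batch gradient descent.
Optimisation uses Adam at learning rate 0.001 with batch size 30 for 15
epochs — a fixed recipe with no early stopping, schedule, or
checkpoint selection.

Evaluation reports class-averaged accuracy (per-class agreement rate,
then unweighted mean over classes), macro F1 (classes with no positives
in labels or predictions are excluded from the mean; micro F1 is also
computed since the two conventions are often conflated), and macro
AUROC via the rank statistic, skipping classes without both a positive
and a negative. The binarization threshold defaults to 0.5.

## Cross-validation

`stratified_kfold()` implements greedy iterative multi-label
stratification: labels are processed from rarest to most frequent and
each positive record goes to the fold with the greatest remaining demand
for that label (ties: most remaining capacity, then a seeded random
draw). The per-class positive counts across the 10 folds are balanced to
within `ceiling(count/10) + 1`. `run_cv()` reseeds weight initialisation
per fold, trains on the remaining folds, and evaluates on the held-out
fold; `sweep_frequencies()` repeats this per sampling rate and
`compare_losses()` runs the two losses with identical seeds and fold
assignments so per-fold differences are paired.

## Augmentation

Two optional, seeded transforms emulate common ECG artifacts, both
scaled by $\sigma$, the standard deviation of all values in the record
(all twelve leads jointly):

* **Additive noise**: each sample receives an independent uniform draw
  on $(-\sigma, \sigma)$.
* **Baseline wander**: one cosine period across the record,
  $A\cos(2\pi i/n + \varphi)$ with $A\sim U(-\sigma,\sigma)$ and
  $\varphi\sim U(0,2\pi)$, one draw shared by all leads (per-lead draws
  are an option). A printed form that places the signal value inside
  the cosine argument exists; it does not produce a low-frequency
  drift, so the index form is the default and the printed form is kept
  behind `variant = "verbatim"` for fidelity testing.

Both transforms are the identity when $\sigma = 0$ and are pure
functions of `(signal, seed)`. Augmentation is applied only during
training and is off by default in all headline runs, consistent with it
not improving held-out performance in our experiments' regime.

## Explanations

LIME treats the trained network as a black box. Each lead's time axis is
cut into contiguous near-equal segments (default 20 per lead, 240
interpretable features). A perturbation keeps each segment independently
with probability 1/2 and replaces masked segments with a reference mean;
the surrogate is a ridge regression of the model's class probability on
the mask indicators, weighted by an exponential kernel on the number of
masked segments (width $0.75\sqrt{F}$). The weighted $R^2$ of every
surrogate is attached to its saliency map and fits below 0.1 are
flagged.

`fit_class_lime()` builds one context per condition by sampling, with
replacement, 1000 records annotated with the condition and 1000
annotated otherwise from the training folds; the context carries the
segment reference means and kernel width reused by all explanations of
that class. Explanations target records *annotated* with the class, not
records predicted positive. `aggregate_lead_importance()` then explains
the validation-fold positives of each class, sums absolute attributions
per lead within each record, and averages the per-record lead totals
into a conditions × 12 matrix (sum and median reducers, signed
attributions, and row-max normalization are options; normalization
cannot change a row's argmax). One mask set is drawn per class and
shared by its records, which makes the aggregate exactly invariant to
record ordering.

## The synthetic generator

`synthetic_spec()` / `generate_corpus()` produce fully seeded corpora of
10-second 12-lead records. Each record is a P-QRS-T-like train of smooth
Gaussian deflections at a per-record heart rate (uniform 50–90 bpm) and
phase, identical across leads up to fixed per-lead gains, plus white
Gaussian sensor noise (default 0.05 mV against an R-deflection of
~1 mV). Labels come from a latent Gaussian copula with equicorrelation
0.1 (a weak positive co-occurrence that exercises the multi-label
paths) thresholded at per-class prevalences. Each active class modifies
*only its assigned lead* with one of four morphology changes: a 1.5×
rate shift, an extra inter-beat deflection, a 2.2× R-amplitude
increase, or a widened-R/delayed-T prolongation. Deflection widths keep
the deterministic waveform effectively band-limited below 12 Hz, so
resampling down to 25 Hz is information-preserving by construction; the
broadband component is only the sensor noise.

Two profiles fix the study conditions: `balanced` (6 classes, uniform
prevalence 0.25) and `challenge_like` (8 classes, prevalences log-spaced
0.5%–35%, mirroring the two-orders-of-magnitude spread of real condition
frequencies in shape, not in exact counts). Signals are quantised to the
1/1000 mV precision of the on-disk container, so the in-memory dataset
and a disk round trip agree exactly.

What the generator deliberately does **not** emulate: realistic ECG
morphology and pathophysiology, inter-lead projection geometry, baseline
drift and powerline artifacts, age/sex-dependent signal structure, and
label noise. Passing tests on these corpora therefore demonstrate that
the pipeline recovers *planted, lead-localised, band-limited* structure
under controlled imbalance — not clinical-grade performance on real
ECGs, whose headline numbers require the multi-gigabyte public challenge
corpus and are far below the synthetic ceiling.

## Problem sizes, numerical choices, and limitations

The test suite and `scripts/acceptance.R` use problem sizes chosen so a
complete run finishes comfortably on one CPU core: the parameter-recovery
experiment trains on 1800 records (one validation fold of a 2000-record
balanced corpus at 75 Hz) for the full 15-epoch recipe; the shuffled-label
null control uses 600 records; the loss comparison uses a 900-record
challenge-like corpus (one fold per arm); lead-importance aggregation
uses 15 segments per lead, 300 perturbations, and up to 6 validation
records per class. These sizes are the package's own desk-scale defaults
for its experiments; the underlying functions accept arbitrary sizes.

Numerical details worth knowing: probabilities are clipped at $10^{-7}$
inside the cross-entropy; the soft-F1 denominator carries the
$10^{-16}$ guard, making the empty-class loss exactly 1; batch-norm uses
$\varepsilon = 10^{-5}$ and momentum 0.1, and inference always uses
running statistics, so per-sample outputs are independent of batch
composition; max-pool ties resolve to the earliest index; the ridge
penalty of the LIME surrogate is $10^{-3}$.

Known limitations: training is CPU-bound and single-threaded beyond
BLAS, so corpus sizes in the hundreds of thousands are out of reach
here; the MAT reader supports the v4 dialect used by the challenge
signal files, not v5/v7; and the explanation machinery assumes the
fixed 12-lead montage.
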