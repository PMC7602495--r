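---
title: "Detecting Parkinsonian tremor from wrist accelerometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Parkinsonian tremor from wrist accelerometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Parkinson's disease tremor is an involuntary oscillation of 3–9 Hz that
appears intermittently during daily life. A wrist-worn triaxial
accelerometer records it together with everything else a hand does:
gravity, posture changes, and voluntary movement whose energy sits mostly
below 3 Hz but which also produces broadband transients (impacts, abrupt
manipulations). `wristtremor` implements a complete detection pipeline for
such recordings — spectral source separation, feature extraction,
supervised and weakly supervised classification, and clinically oriented
evaluation — together with a synthetic cohort generator that makes every
stage testable without clinical data. This vignette explains the models,
the tunable parameters, and the design decisions that were genuinely open.

## Preprocessing

Recordings are resampled to 50 Hz (tremor and its first two harmonics lie
well below the 25 Hz Nyquist). Exact integer ratios use zero-phase FIR
decimation; other integer rates go through polyphase resampling. Gravity is
removed by a third-order Butterworth high-pass at 0.3 Hz applied
forward–backward. Zero-phase filtering is a deliberate choice: analysis is
offline, and a causal filter would delay the signal by its group delay and
shift window labels relative to the annotated event boundaries. Odd
reflection padding (10 s) suppresses the forward–backward edge transient.

The signal is then cut into 3-second windows (150 samples) with a 1-second
hop. The first window starts at the first sample; a trailing partial window
is discarded. A window is labeled tremor when *strictly more than half* of
it (>1.5 s) overlaps an annotated tremor interval; exactly half counts as
non-tremor, a tie rule chosen to read the labeling criterion literally.

All spectral representations share one grid: the tapered 150-sample window
is zero-padded to 256 points and the one-sided bins 0–127 cover 0–24.8 Hz
in steps of 50/256 Hz. Welch power spectral densities (three 75-sample,
50%-overlapping Hamming segments), the factorization dictionaries, and the
stacked CNN inputs all live on these 128 points, so the modules compose
without regridding.

## Non-negative tremor factorization

The core of the package is an unsupervised decomposition of each window's
per-axis amplitude spectrum \(S\) into a tremor part and a non-tremor part,

\[
\hat S \;=\; \underbrace{\Big(\sum_i w^t_i\, t_i(f)\Big)\odot\Big(\sum_j w^h_j\, h_j(f)\Big)}_{S_\text{tremor}\;=\;S_\text{source}\,\odot\,S_\text{shape}}
\;+\; \underbrace{\sum_j w^a_j\, a_j(f)}_{S_\text{non-tremor}},
\]

a source–filter model in the style of voice-extraction NMF. The source
dictionary \(T\) holds 60 "ideal" tremor spectra with base frequencies every
0.1 Hz on \([3, 9)\) Hz — the half-open grid is what makes exactly 60 rows —
plus an all-ones row for motionless windows. Each ideal spectrum is the sum
of three rectified sinc lobes at \(f_0, 2f_0, 3f_0\) with amplitudes
\(1, \tfrac12, \tfrac14\). The shape dictionary \(H\) (and the identical
non-tremor dictionary \(A\)) holds 63 Hann bumps of width five grid points
at 50% overlap, whose sum is 1 everywhere.

**Lobe width.** The tremor atoms keep only the *main lobe* of the rectified
sinc, truncated at its first zeros, with half-width one grid step
(50/256 Hz). This was the one genuinely consequential open choice. With
wide, overlapping sinc tails the model is barely identifiable: the free
Hann basis fits broad structure just as well as the tremor part, and within
a fixed iteration budget it absorbs most of the tremor energy; rows whose
harmonics coincidentally overlap a peak also acquire weight, corrupting any
frequency estimate. Near-impulsive atoms make the tremor part the only
component that can explain sharp harmonic peaks cheaply, which is exactly
the prior the model encodes.

**Optimization.** The weights minimize \(\lVert S-\hat S\rVert^2\) by
multiplicative updates derived from the Euclidean objective — each block's
update multiplies by the ratio of the positive to the negative part of its
gradient, e.g.

\[
w^t \leftarrow w^t \odot
\frac{\big(S_\text{shape}\odot S\big)\,T^\top}{\big(S_\text{shape}\odot \hat S\big)\,T^\top},
\]

and analogously for \(w^h\) (with \(S_\text{source}\) in both numerator and
denominator) and \(w^a\) (with plain \(S\) and \(\hat S\)). The
reconstruction is recomputed after every block update. Weights start at 1
(deterministic, no seed); denominators are floored at `1e-12` to avoid 0/0;
100 iterations are run, after which the objective has long stopped moving
perceptibly. Non-negativity is preserved by construction and the per-block
updates are monotone, which the test suite verifies to a relative tolerance
of `1e-9` on random spectra. After the last iteration the weight of the
all-ones row acts as a threshold: every tremor weight below it is zeroed.
This makes weight comparability across rows essential, which is why all
rows peak at 1.

**Personalization.** Given a subject's windows, the average power spectrum
(mean of squared amplitude spectra over windows and axes) reshapes the 60
tremor atoms by elementwise multiplication, and the base frequency \(f_0\)
is the highest strict local maximum of that average inside 4–8 Hz. Each
reshaped row is then renormalized to unit maximum. Without renormalization,
rows reduced to tiny clipped fragments of the subject's peak take enormous
compensating weights, and both the ones-row threshold and the subsequent
"keep the three largest weights within \(f_0 \pm 1\) Hz" constraint —
which compare raw weight magnitudes — become meaningless. The constraint
itself is applied once, after thresholding: applying it inside the loop
would freeze the support, since multiplicative updates cannot revive a
zeroed weight. Ties break toward the lower base frequency. Degenerate
inputs (all-zero or peakless average spectra) refuse personalization with a
warning rather than guessing.

The factorized tremor spectrum yields two things downstream: the per-window
**tremor energy** (sum over axes of squared tremor amplitudes), used as an
unsupervised ranking, and the **T/NT spectra** (total, tremor, non-tremor
per axis) consumed by the cepstral and CNN feature sets.

## Feature sets

Five hand-crafted sets, each with a fixed, tested dimension:

* **energy (1):** summed squared spectrum in 3–9 Hz — the classical
  benchmark a simple threshold detector would use.
* **psd (384):** Welch PSD, 128 points per axis.
* **baseline (356):** 16 time-domain and 27 frequency-domain features on
  each of x, y, z and the magnitude channel of acceleration and jerk
  (first difference × sample rate), plus 12 inter-axis correlations.
  Quantities the literature leaves underspecified are pinned here: IQR(2)
  is the 25th/75th percentiles; ECDF(4) the 0.2/0.4/0.6/0.8 quantiles;
  time-domain entropy is Shannon entropy of a 16-bin histogram of \(|x|\)
  (spectral entropy uses the L1-normalized spectrum); AR(2) are Yule–Walker
  coefficients with a zero fallback for constant signals; dominant
  frequency is the spectral argmax, average frequency the centroid, and the
  six band energies use equal-width bands over 0–25 Hz. Correlations of
  constant channels are defined as 0, so the vector is finite for any
  input.
* **mfcc (36):** 12 cepstral coefficients per axis from the
  Hamming-tapered spectrum. The mel filterbank is rescaled to this signal
  class: 26 triangular filters mel-spaced over 0.3–25 Hz, evaluated as
  continuous triangles on the grid (no integer-bin snapping, so no filter
  is empty), log floored at `1e-10`, orthonormal DCT-II, keeping c1–c12.
  Excluding c0 makes the features invariant to overall signal scale — a
  deliberate trade: robustness to amplitude calibration at the cost of
  discarding the amplitude cue.
* **mfcc_tnt (108):** the same cepstral pipeline applied to the total,
  tremor and non-tremor spectra of each axis (the FFT stage is skipped
  since spectra are given). This is the package's flagship hand-crafted
  set: separating the tremor spectrum first is what lets cepstra describe
  *tremor* shape rather than whole-motion shape.

## Classifiers

The supervised baselines are a 100-tree random forest and a multi-layer
perceptron (128 → 32 → 1, ReLU/ReLU/sigmoid) trained with binary
cross-entropy, rmsprop (learning rate `1e-3`, the conventional default),
batch size 50, and dropout 0.2 after the hidden layers. The epoch count is
chosen on a validation subset (20% of training windows, subject-stratified)
with early stopping at patience 5. MLP inputs are z-scored on training
statistics stored in the model — feature blocks with spreads differing by
an order of magnitude otherwise stall rmsprop. Training is deterministic
given a seed; identical seeds reproduce identical predictions.

Two small convolutional feature learners are implemented directly as
im2col matrix operations. The **raw** architecture applies 16 length-25 1D
kernels per axis ("same" padding), max-pools by 4, and flattens to 1776
features under a 128/64/32/1 dense head. The **tnt** architecture stacks
the nine T/NT spectra into a 9 × 128 image, applies 32 kernels of 3 × 9 and
16 of 3 × 5 (valid), and treats the second convolution's 9280 outputs as
the learned features under a 128/32/1 head. Kernel counts and dense widths
were chosen to keep parameters small relative to synthetic-cohort sizes.
Convolution kernels are initialized from a three-layer autoencoder trained
for 10 epochs on sampled patches (the encoder weights become the kernels);
all other layers are Glorot-uniform. A practical caveat the test suite
encodes: with only a handful of training subjects, the tnt network can
latch onto the training subjects' base frequencies and generalize poorly to
an unseen \(f_0\); learned spectral features are data-hungry, so at test
scale the suite asserts parity with, not dominance over, the energy
benchmark.

## Weak supervision (multiple-instance learning)

In-the-wild labels are 5-minute diary entries with three levels: *almost
none*, *half the time*, *almost always*. The MIL loop turns them into
window-level pseudo-labels: rank the windows of each entry by the current
model's scores; select the bottom 50% (labeled 0) for *almost none*, the
top 50% (labeled 1) for *almost always*, and the bottom and top 25% for
*half the time*; retrain the base classifier on the latest selections only;
repeat. Counts use `floor` with a minimum of 1, sorting is stable with ties
broken by window index, and entries with fewer than four windows are
skipped with a warning. Because no model exists at the start, the first
ranking uses the factorized tremor energy — unsupervised, label-free, and
the reason the loop starts close to a good solution.

The stopping rule had to be pinned: 20% of entries (subject-stratified)
are held out, each iteration's model predicts every held-out entry's weak
label via its detected tremor percentage, and the kept iteration maximizes
the Spearman correlation with the reported labels; the loop stops after two
non-improving iterations. Retraining from the latest selections only (not
accumulating) follows the three-step loop structure directly.

## Evaluation

All performance is leave-one-subject-out: one fold per subject, the
aggregate is the *mean of per-subject AUCs*, never the pooled-window AUC.
ROC curves slide the threshold over all distinct scores; AUC is the
trapezoidal area (identical to the Mann–Whitney statistic, which the tests
verify pair-by-pair), and the false-positive rate at 90% sensitivity is
linearly interpolated between adjacent ROC points — a stepwise convention
would systematically overstate it. AUC differences can be tested with the
Hanley–McNeil standard error and an independent two-sided z-test.

Tremor percentages map to diary labels by <33% / 33–66% / >66%, with both
boundaries inclusive to *half the time*, and back to midpoints 16.6%, 50%,
83.3%. Agreement between predicted and reported labels is Spearman's rank
correlation with average ranks, flagged undefined for constant sequences.
The monitoring biomarker — percentage of tremor time per period — is the
fraction of tremor-predicted windows; on synthetic data its error against
the generator's ground truth shrinks as the aggregation period grows, and
with an oracle classifier it matches the generated fraction to within the
discretization error of windowing.

## The synthetic cohort generator

The generator is first-class, tested code; it defines the study conditions
under which everything above is exercised. Each subject draws a profile:
base frequency in 4–8 Hz, tremor amplitude 0.08–0.3 g with harmonic decay,
burst duration 5–15 s, ADL level 0.05–0.12 g RMS, and a tremor prevalence
placed on an even spread from 3% to 70% so every cohort contains both a
barely affected and a severely affected subject. A recording (100 Hz, so
the 2:1 resampling path is always exercised) is the sum of:

* a gravity vector with slow (<0.1 Hz) orientation drift,
* band-limited (0–3 Hz, 4th-order Butterworth) background motion,
* broadband ADL transients — Poisson-arriving (0.1/s), exponentially
  damped noise jolts of 0.2–0.6 s reaching a sizable fraction of 1 g.
  These matter: without them, in-band energy is an essentially perfect
  detector by construction and no comparison against the energy benchmark
  can say anything. Real daily activity does put energy into 3–9 Hz,
  and the transients are the generator's stand-in for it,
* tremor bursts: sinusoids at \(f_0\) (±0.05 Hz jitter) with two
  harmonics, random phase per axis, Hann on/off ramps of 0.5 s, with
  Poisson-distributed starts and gamma-distributed durations calibrated so
  the long-run burst fraction matches the profile prevalence,
* white sensor noise (0.01 g).

Diary entries cover the five minutes before each prompt; the true tremor
fraction maps through the 33/66 rule, and with probability `label_noise`
(default 5%) the label shifts one level. All randomness flows from one
seed; identical seeds reproduce recordings bit for bit.

What the generator does *not* emulate: the temporal structure of real
activities (cooking vs. typing), postural tremor versus rest tremor,
dyskinesia, device artifacts (clock drift, saturation), or hand asymmetry.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that its comparative behavior holds under the stated spectral
assumptions — not that clinical-grade accuracy would be achieved on real
patients.

## Problem sizes and numerical conventions

The default study cohort is 6 subjects × 2 hands × 20 minutes with
5-minute diary entries (48 entries, ≈14,000 windows); the discrimination
and MIL suites run on it, while unit tests use 3–5 subject cohorts of
3–5 minutes per hand. These sizes were chosen so the full pipeline —
factorization included — runs comfortably on a single CPU while leaving
every qualitative behavior (LOSO discrimination, MIL convergence in a
handful of iterations, percentage-of-tremor-time recovery) measurable.
Degenerate-input conventions are collected here: zero windows produce zero
spectra and zero features; constant channels get correlation 0 and AR
coefficients 0; all-zero spectra factorize to all-zero weights; exactly-50%
window overlap is non-tremor; 33% and 66% both map to *half the time*; ties
in instance selection resolve by window index, and ties among tremor
weights toward the lower base frequency.

## Known limitations

The factorization's tremor/non-tremor split is identifiable only because
the tremor atoms are near-impulsive; a future dictionary learned from data
would need an explicit disjointness penalty. MFCC scale-invariance
discards amplitude, which carries real information when devices are
calibrated. The CNN feature learners need more subjects than a desk-scale
cohort provides before their advantage over hand-crafted cepstra can
materialize. And the weak-label machinery assumes diary entries are
honest up to one level of noise; systematic over- or under-reporting is
not modeled.
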