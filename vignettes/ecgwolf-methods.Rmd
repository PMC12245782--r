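---
title: "ecgwolf: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecgwolf: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the scientific and numerical decisions behind the
package: what each stage computes, which parameters matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## The pipeline and its assumptions

The package classifies fixed-length ECG windows into five rhythm classes
(1 atrial fibrillation, 2 supraventricular tachycardia, 3 bradycardia,
4 premature ventricular contractions, 5 atrial flutter). The processing
chain is: min-max normalization, zero-phase 0.5–40 Hz band-pass,
windowing, feature extraction, wrapper feature selection with a KNN
cross-validation fitness, LSTM classification, one-shot test evaluation.

Assumptions worth making explicit:

* **Single channel.** All formulas operate on one waveform. Multi-channel
  sources contribute one user-selected channel (default the first);
  cross-lead fusion is out of scope.
* **Window-level labels.** A window inherits the label of the annotation
  nearest its center (ties break toward the earlier annotation). Windows
  without any annotation are unlabeled and dropped. This means a window
  from a PVC record that happens to contain only normal beats is still
  labeled PVC — label noise that real per-beat annotation would avoid.
* **Sample-level splitting.** The randomized 70–15–15 split operates on
  windows, not recordings, mirroring the common (leak-prone) protocol; a
  stratified mode (`stratified_split = TRUE`) is provided, and users
  working with real multi-record data should split at the record level
  before segmentation.
* **Leakage protocol.** Feature selection is fitted on the training split
  only (its 5-fold CV is internal to that split); the validation split
  steers early stopping; the test split is consumed exactly once.

## Preprocessing

**Normalization** implements the min-max map onto $[0,1]$ literally;
a `range = c(-1, 1)` option rescales for users who prefer a symmetric
convention. A constant signal is a degenerate-input error (the denominator
is zero), never silently imputed. NaN/Inf samples are rejected at
ingestion everywhere.

**Band-pass filter.** The filter is *defined* in the frequency domain
($Y(f) = H(f)\,X(f)$) and is applied there: the signal's FFT is multiplied
by the analytic order-$n$ Butterworth band-pass magnitude
$$|H(f)| = \Big(1 + \big(\tfrac{f^2 - f_1 f_2}{(f_2-f_1)\,f}\big)^{2n}\Big)^{-1/2},$$
with $f_1 = 0.5$ Hz, $f_2 = 40$ Hz, $n = 4$ by default. This realization
is exactly zero-phase (beat morphology is not skewed) and exactly linear.
A time-domain recursive (filtfilt) realization of this band at 360 Hz was
measured to lose ~6 decimal digits to pole clustering near the unit
circle, so the spectral form is also the better-conditioned choice. The
trade-off is circular (periodic) boundary handling; on records of tens of
seconds the wrap-around transient is negligible, and windows are cut after
filtering the whole record.

**QRS detection** follows the classic energy-based recipe: 5–18 Hz
band-pass, first difference, squaring, 150 ms moving-average integration,
a threshold at 20% of the integrated maximum, peak refinement to the local
signal maximum, and a 0.2 s refractory period. This is intentionally
simple — on the generator's morphology it recovers planted beats to within
a few samples — and is not tuned for pathological real-world noise.

## Features

Per window (360 samples at the defaults) the registry is: energy; mean,
population variance (divisor $N$ — the source convention), median, max,
min, RMS; wavelet sub-band energy and variance; four co-occurrence texture
measures. That is $1 + 6 + 2(L+1) + 4 = 21$ columns at the default
$L = 4$ levels.

**Wavelets.** The decomposition is a periodized orthogonal DWT (db4,
8 taps, 4 levels), implemented in the package because no wavelet library
is among the dependencies. Orthogonality gives exact energy partitioning
(Parseval), which the tests assert to 1e-8; odd-length levels are
zero-padded by one sample, which adds no energy. Only analysis is
implemented — features are sub-band summaries, nothing is reconstructed.

**Co-occurrence texture on a 1-D signal.** The texture matrix is built
from pairs of amplitude-quantized samples $(q_t, q_{t+\text{lag}})$
(default 8 levels, lag 1, symmetrized), the natural 1-D reading of an
image technique. A constant window occupies a single cell: contrast 0,
energy 1, homogeneity 1, and correlation undefined (such rows are dropped
with a message). A spectrogram-image variant was considered and rejected
as out of scope.

**LDA** is available as an optional, off-by-default projection to at most
$C-1$ discriminants computed from the between/within scatter problem; the
within-class scatter is regularized by $\varepsilon I$ with
$\varepsilon = 10^{-6}\times$ the mean diagonal so small fixtures remain
solvable. It is off by default because the wrapper search below operates
most informatively on the raw, nameable features.

## The gray-wolf wrapper search

Each wolf is a bit vector over feature columns. Fitness is the mean
stratified 5-fold cross-validated accuracy of a $k{=}5$ nearest-neighbour
classifier restricted to the selected columns — pure accuracy, no
feature-count penalty; parsimony enters only through tie-breaking
(equal fitness prefers fewer features, then the earlier-seen mask). Folds
are assigned once per run, so fitness is a deterministic function of the
mask.

Defaults: 30 wolves, 100 iterations, 30 bits set at initialization
(capped at the feature count), exploration parameter $a$ decaying linearly
from 2 at the first iteration to 0 at the last. The continuous gray-wolf
update toward the three best-ever leaders is retained between iterations;
binarization happens through the sigmoid transfer
$S(x) = 1/(1+e^{-\lambda(x-0.5)})$ with $\lambda = 10$ (a standard
binary-GWO transfer; the steepness is exposed in the configuration).
Degenerate all-zero masks are repaired to a uniformly random mask whose
popcount is uniform on $\{1..\min(\text{init\_k}, d)\}$. When the initial
population is saturated (init\_k $\ge d$ makes every wolf identical),
unfilled leader slots fall back to the best mask.

The search is elitist by construction — the $\alpha$ fitness never
decreases — and its evaluation budget is exactly
$\text{num\_wolves} \times (\text{max\_iter}+1)$. A binary PSO (inertia
0.9→0.4, both accelerations 2, velocity clamped to $\pm 4$, the same
transfer and budget) and a budget-matched random search provide
convergence baselines.

## The LSTM head

Each window's selected feature vector is a length-1 sequence into a
50-unit LSTM whose cell is written out from the gate equations; an
alternative mode feeds the raw sample window as a $T\times 1$ sequence for
users who want genuinely temporal input. The head is: LSTM (last output)
→ dropout 0.2 → dense(5) → softmax, trained with cross-entropy under Adam
(learning rate 0.01, batch 100, up to 30 epochs, L2 weight decay 0.001 on
weight matrices, He-normal initialization, biases zero).

Numerical choices:

* Features are z-scored per column on the training split (the statistics
  travel with the model); the registry mixes energies in the hundreds with
  texture values below one, and unscaled inputs stall gradient training.
* Gradients are clipped to global norm 1.0: 0.01 is a high learning rate
  for Adam and clipping prevents occasional divergence without changing
  the converged solutions in our tests. Training aborts with the epoch
  index if the loss ever becomes non-finite.
* Softmax is computed with max-shift; probabilities are exact to the
  shift-invariance of the definition.
* Early stopping monitors validation loss once per epoch and stops after
  6 checks without improvement (30 maximum epochs with patience 6
  reconciles the fixed-epoch and validation-check accounts of the training
  recipe); the best-validation weights are restored.
* Everything is seeded: initialization, batch order, dropout masks. Two
  runs with the same data and seed are bit-identical.

## Evaluation

Multi-class sensitivity and specificity are computed one-vs-rest per class
and macro-averaged (unweighted mean), with per-class values always
reported alongside — single-number summaries hide which rhythm is failing.
A class absent from the truth has undefined sensitivity; it is excluded
from the macro mean with a warning. ROC curves sweep the unique scores as
thresholds with (0,0) and (1,1) endpoints and trapezoidal AUC — equivalent
to the tie-corrected Mann–Whitney statistic, which the tests assert. The
error histogram bins $P(\text{true class}) - 1$ into 20 equal-width bins.
Paired model comparison uses McNemar's exact test on discordant pairs
(the standard paired-classifier test; chosen because the comparison's
original test is unnamed), with $p = 1$ when no discordant pairs exist.

## The synthetic generator

The generator exists so that every stage has analytic ground truth. Beats
are sums of Gaussian bumps (P, Q, R, S, T); RR intervals are log-normal
with class-dependent mean and coefficient of variation; class flags apply
the clinical signatures: AFib suppresses P waves and has CV 0.25 at mean
RR 0.75 s; SVT is fast and regular (0.35 s, CV 0.03); bradycardia is slow
(1.4 s); PVC inserts wide-QRS ectopics at rate 0.25 with a compensatory
pause; flutter adds a 4.5 Hz sawtooth baseline at mean RR 0.6 s.
Observation noise is Gaussian, sd 0.05 mV against a 1 mV R peak. These
values are standard clinical ballpark figures chosen once; the mean-RR
ordering SVT < {AFib, PVC, flutter} < bradycardia is asserted across
seeds.

The planted feature table for selection benchmarks uses five informative
columns, where column $j$ separates class $j$ from the rest by 4
within-class standard deviations, plus 45 standard-normal noise columns,
with shuffled column order. The one-vs-rest construction makes the
informative set *jointly necessary* — no strict subset separates all five
classes — so recovering all of it is rewarded by fitness, not just by
luck; with all 50 columns the KNN fitness still exceeds 0.95, and with
noise-only masks it sits at the 0.2 chance level.

What the generator does **not** emulate: real measurement artifacts
(electrode motion, baseline wander beyond a sawtooth, muscle noise),
inter-patient morphology variability, class imbalance, and ambiguous
rhythms. Passing the synthetic benchmarks therefore demonstrates that the
implementation is correct and the pipeline is coherent — not that the
method achieves any particular clinical accuracy. Applying the pipeline to
MIT-BIH recordings additionally requires a user-chosen mapping from beat
annotations to the five rhythm classes, which the package deliberately
does not hard-code.

## Problem sizes

The shipped configurations use 100 one-second windows per class (500
total, split 350/75/75) for end-to-end runs and selection benchmarks of
50 features × 500 rows at 30 iterations; at these sizes a full pipeline
run takes well under a minute on one CPU. Orchestration tests run reduced
variants (30 windows per class, 8–10 iterations) since they check
plumbing, not accuracy. All sizes are configuration values, not constants.

## Known limitations

* The QRS detector is threshold-based and untuned for severe noise.
* Texture features depend on the quantization level count; 8 levels is a
  reasonable default for 1-second windows but was not optimized.
* The LSTM sees length-1 sequences by default, so its recurrence is
  exercised only in the optional raw-window mode.
* WFDB support covers formats 16 and 212 and the standard annotation
  stream — enough for the MIT-BIH layout, not the full format family.
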