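---
title: "Methods: automated resting-state EEG spectral analysis and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated resting-state EEG spectral analysis and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state EEG slows in Alzheimer's disease: relative power shifts from
the alpha and beta bands toward theta. `eegpsd` implements a fully
automated pipeline that turns brief (minutes-long) multi-channel
resting-state recordings into scale-free spectral features, tests them
between a patient and a control group, and cross-validates a transparent
logistic-regression classifier on the few most discriminative features.
Every stage is deterministic given its inputs and a seed, and a synthetic
cohort generator with known ground truth makes the whole chain testable
without clinical data.

## Pipeline

For each subject, in fixed order:

1. **Montage selection.** Keep the 14 channels `Fp1 Fp2 F7 Fz F8 T7 C3 Cz
   C4 T8 P7 P8 O1 O2` (configurable), reordered to montage order. Channel
   order is load-bearing: it defines feature-column identity downstream.
2. **Resampling** to a common 250 Hz by polyphase rational resampling
   (`signal::resample`); 1000 Hz uses the ratio 1/4 and 1024 Hz the exact
   ratio 125/512. Upsampling is refused.
3. **Band-pass filtering** 3–35 Hz, zero phase (below).
4. **Bad-channel screening.** A channel is dropped when |amplitude|
   exceeds 500 µV in more than 10% of samples, or its SD falls below
   0.1 µV — conventional clinical EEG bounds, both configurable.
5. **Epoching** into non-overlapping 1-s windows; a trailing partial
   window is discarded. At 250 Hz a 1-s epoch has exactly L = 250 samples,
   so DFT bins fall on integer Hz and "the bin at f Hz" is unambiguous.
6. **Artifact screening** per (channel, epoch): five summary features
   (max |amplitude|, variance, line length, excess kurtosis, fraction of
   power above 20 Hz) feed either a trained SVM or a deterministic
   amplitude rule (flag when max |amplitude| > 100 µV). Decisions are per
   channel, not per whole epoch across channels, because the usability
   rule below is channel-wise.
7. **Clean-duration gate.** A channel is usable only if at least 90 s
   (1.5 min) of its epochs are artifact-free; the bound is inclusive. A
   subject with no usable channel is excluded and counted.
8. **Spectral features.** Per clean epoch, the two-sided periodogram
   \(P(f) = \frac{1}{L F_s}\bigl|\sum_{n=0}^{L-1} x(n)\,
   e^{-j2\pi f n/F_s}\bigr|^2\); epochs are averaged per channel first,
   then the averaged spectrum is normalized by the sum of the integer bins
   3–30 Hz inclusive (28 bins). Band powers are means of normalized bins
   over delta 1–4, theta 5–9, alpha 10–13, beta 14–32 Hz; an all-channel
   montage mean is the per-subject summary.
9. **Statistics and selection.** Per feature — the normalized power at
   each (channel, bin) pair for bins 5–11 Hz inclusive, 7 × 14 = 98
   columns — a two-tailed unpaired Welch t-test compares groups (sign
   convention HC − AD). The k = 4 features with smallest p are selected.
10. **Classification.** L2-regularized logistic regression (AD = positive
    class), stratified 5-fold cross-validation, features standardized with
    training-fold statistics only. Reported metrics are pooled out-of-fold:
    accuracy = correct predictions / all subjects, rank AUC over pooled
    probabilities, precision and recall — all as percentages.

## Design choices where the design was open

**Filter.** The corner frequencies (3 and 35 Hz) leave the family open. An
IIR Butterworth of modest order applied forward–backward cannot hold
passband droop under 1 dB close to the 35 Hz corner (an order-4 design is
≈3 dB down at 32 Hz after two passes), so the package uses a linear-phase
windowed-sinc (Hamming) FIR band-pass with ~2 Hz transition bands, applied
once by FFT convolution with the group delay compensated exactly. This
gives >50 dB stopband attenuation (DC, line noise, and everything beyond
37 Hz), <0.1 dB passband ripple, and strictly zero phase distortion.

**"Paired" is impossible between groups of unequal size**, so the group
comparison is the unpaired two-sample t-test; Welch by default (no
equal-variance assumption), pooled-variance Student as an option. No
multiple-testing correction enters selection — features are ranked by raw
p, which is the procedure being replicated — but a Benjamini–Hochberg
column is reported alongside for transparency.

**Tie-breaking in selection** (equal p) is deterministic: larger |t|,
then montage order, then ascending bin.

**Delta band vs the 3 Hz high-pass.** The nominal delta band (1–4 Hz)
conflicts with the 3 Hz high-pass; delta is computed from the surviving
3–4 Hz bins and flagged `partial`. The beta band (14–32 Hz) extends past
the 30 Hz normalization ceiling; bins 31–32 are normalized by the 3–30 Hz
sum but included in the beta mean, reading both definitions literally.

**Selection leakage.** `selection_mode = "full-cohort"` selects features
on all subjects before cross-validation — the replicated procedure, which
is optimistically biased under the null. `"nested"` re-runs selection
inside every training fold. Both are exposed so the bias is measurable;
the test suite measures it on null cohorts.

**Hyperparameter search.** The default grid spans C ∈ {0.01, 0.1, 1, 10,
100}; ties go to stronger regularization. The grid is evaluated on a fold
split derived from, but distinct from, the final scoring split (shuffle
seed + 1), so the chosen C is never the maximum taken over the same
partition it is scored on.

**Logistic solver.** The fit is a penalized Newton (IRLS) solver
minimizing −loglik + ‖w‖²/(2C) with an unpenalized intercept, so C has
its conventional inverse-regularization meaning, single-feature designs
work, and separable data stay finite. The test suite cross-checks the
coefficients against an independent ridge-regression implementation
(`glmnet` at λ = 1/(nC)) and the rank AUC against `pROC`.

**Missing features** (excluded channels) are imputed with column means
computed without group labels, so imputation cannot leak the outcome.

## The synthetic cohort generator

Each subject–channel is a stationary Gaussian process with target
one-sided spectrum

\[ S(f) = \frac{1}{\max(f, 0.5)^{e}} + \sum_b (w_b j_b)^2\,\phi_b(f), \]

a 1/f^e background (e = 1 by default) plus raised-cosine bumps φ_b over
the four bands with profile weights w_b and per-subject log-normal
jitters j_b (SD 0.15). Realizations come from frequency-domain shaping of
white noise — one FFT per channel — scaled so expected channel RMS is
10 µV times a log-normal per-channel gain (SD 0.1). The default profiles
plant the canonical slowing contrast: the control profile is
alpha-dominant (weights delta 0.6, theta 0.9, alpha 1.9, beta 0.45), the
disease profile raises theta to 1.35 and lowers alpha to 1.25 and beta to
0.30. `profile_ad(effect)` scales the planted log-ratio geometrically, so
`effect = 0` is an exact null and `effect > 1` exaggerates the contrast.

**Artifacts** are Poisson events per channel (2/min by default), 0.5 s
long, at 20 × channel RMS (≈200 µV over the 10 µV background — typical of
ocular and movement artifacts): "ocular" events are trains of sharp
biphasic deflections (~50 ms lobes, blink-like, low-frequency); "muscle"
events are 20–45 Hz noise bursts. A short-taper envelope keeps near-full
amplitude across the event, so every epoch the event overlaps carries
detectable energy — matching the conservative ground-truth rule that any
sample overlap marks the epoch. Amplitudes, durations, and morphologies
are simulator conventions chosen for physiological plausibility, not
claims about any particular dataset.

**What the generator does not emulate:** volume conduction and
between-channel correlation, non-stationarity (drowsiness, drifts),
realistic artifact topographies (ocular artifacts dominate frontal
channels in real data; here every channel draws from the same process),
and line noise. Passing tests therefore demonstrate that the pipeline's
machinery is correct and calibrated on data with the assumed statistical
structure — not that the classifier's numbers transfer to clinical
recordings.

## Numerical conventions and degenerate inputs

- The periodogram is two-sided with no one-sided doubling; the 3–30 Hz
  normalization cancels any constant convention factor. Parseval's
  identity (Σ P(f)·F_s/L = mean x²) holds to 1e−9 and the implementation
  matches a direct DFT oracle to 1e−10 relative error.
- Normalized spectra sum to 1 over bins 3–30 inclusive to 1e−9, including
  after artifact-masked averaging and montage averaging (the constraint is
  linear); all features are invariant to global amplitude rescaling.
- Constant feature columns are flagged `degenerate` (t = 0, p = 1 when
  group means agree; NA otherwise). All-zero channels fail normalization
  with an explicit error. Excess kurtosis of a constant epoch is defined
  as 0.
- Determinism: every stochastic step takes a seed; per-subject seeds are
  a stable hash of (cohort seed, subject index), so cohorts are
  reproducible and subjects independent of cohort size.

## Problem sizes used by the test suite

The structural-count and effect-direction checks run the study-sized
design (23 + 18 subjects, 14 channels; 300 s and 60 s recordings
respectively). The calibration and resampling suites use scaled-down
replicates chosen for statistical power at practical runtime: null
calibration uses 200 cohorts of 10 + 10 subjects × 30 s with subject-level
spectral variability switched off, which makes the 98 false-positive
counts binomial (with subject-level variability the per-replicate
fractions stay centred on 0.05 but are over-dispersed because features
within a band share the subject's jitter); the permutation-null and
effect-monotonicity checks use 200 and 3 × 50 replicates at 30 s and 20 s.
Artifact-detector quality is evaluated held-out: the SVM is trained on one
synthetic cohort's ground truth and scored on a fresh cohort.

## Known limitations

- The artifact SVM re-implements the published contract (five features, a
  margin classifier, a deterministic fallback) but not any particular
  trained model; absolute sensitivity/specificity on real data will
  depend on training labels.
- Welch and permutation p-values agree closely for these sample sizes,
  but with n < ~8 per group the t-approximation degrades; the package
  does not implement an exact test.
- The full-cohort selection mode replicates a procedure with known
  optimism under the null; use `"nested"` for unbiased estimates.
- Clinical effect sizes, exact band means, and classifier metrics from
  any private dataset are not reproducible here; the synthetic defaults
  target direction and detectability, not effect magnitudes.
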