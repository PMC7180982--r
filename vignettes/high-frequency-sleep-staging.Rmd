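---
title: "Muscle tone from high-frequency EEG: models and methods in sleephf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle tone from high-frequency EEG: models and methods in sleephf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Visual sleep staging assigns one of five labels (Awake, REM, N1, N2, N3)
to every 30-s polysomnography epoch. EEG alone separates most stages, but
REM and N1 look almost identical on EEG: both are low-amplitude,
mixed-frequency states. Human scorers disambiguate them with the chin
EMG — muscle tone is absent in REM (atonia) and present in N1 — so
EEG-only automatic scorers systematically confuse the two.

Scalp EEG electrodes, however, sit over scalp muscle. Surface EMG is a
broadband signal (roughly 25–500 Hz) that is orders of magnitude larger
than EEG, and part of it leaks into EEG leads. When EEG is sampled at
500 Hz and *not* low-pass filtered for display, its 80–250 Hz content is
dominated by this leaked muscle activity, while 35–80 Hz is a mixture of
genuine gamma-band brain activity and muscle. The package's premise is
that this "noise" is a usable muscle-tone surrogate: keeping the
high-frequency EEG content should specifically improve REM-vs-N1
discrimination in an EEG-only scorer.

`sleephf` implements the full pipeline — signal I/O, preprocessing,
feature extraction, two-channel fusion, classification, evaluation — and
a synthetic polysomnography generator that makes every stage of the
pipeline testable without access to clinical recordings.

## Pipeline overview

For each 30-s epoch and each of two EEG channels:

1. **Preprocessing.** A 60 Hz zero-phase notch (second-order IIR, Q = 30)
   and nothing else: no detrending, no artifact rejection. The scattering
   features are stable to the slow drifts and transients that detrending
   and artifact rejection normally target, and any further filtering
   would touch the high-frequency band under study.
2. **Scattering features.** An order-2 wavelet scattering transform of
   the 90-s context window (the epoch plus the preceding 60 s, reflecting
   the serial dependence of stages). Coefficients are globally averaged
   over the window and log-transformed.
3. **High-band STFT features** (unfiltered runs only). `log10` Welch band
   energies of the current 30-s epoch over (35,80), (80,150) and
   (150,250) Hz, concatenated to the scattering vector.
4. **Fusion.** Per-feature standardization (training statistics only),
   then CCA across the two channels; the fused vector concatenates both
   k-dimensional projections.
5. **Classification.** RBF-kernel SVM, one-vs-one multiclass, class
   weights inversely proportional to class frequency.
6. **Evaluation.** Leave-one-subject-out cross-validation; pooled 5×5
   confusion matrix; per-class precision/recall/F1, overall accuracy,
   Cohen's kappa, and macro F1 (the unweighted mean of the five F1s).

The filtered/unfiltered contrast is run as a pair: the "filtered" arm
low-passes the EEG at 50 Hz first (the clinical export) and uses
scattering features only; the "unfiltered" arm uses the raw signal and
appends the three high-band energies. Everything else is identical, so
metric differences isolate the high-frequency contribution.

## The scattering transform

The transform iterates wavelet convolution and modulus. With analytic
band-pass filters $\psi_\lambda$ and a low-pass $\phi$:

- order 0: average of the low-passed window;
- order 1: $S_1(\lambda_1) = \mathrm{mean}\,|x \star \psi_{\lambda_1}|$;
- order 2: $S_2(\lambda_1, \lambda_2) =
  \mathrm{mean}\,||x \star \psi_{\lambda_1}| \star \psi_{\lambda_2}|$,
  restricted to $f_c(\lambda_2) < f_c(\lambda_1)$.

Defaults: Gaussian (Morlet-type) filters, `Q1 = 8` per octave over
`J = 10` octaves descending from Nyquist (80 first-layer filters,
0.26–250 Hz at 500 Hz sampling), `Q2 = 1`, global averaging, natural-log
transform with a `1e-12` floor. The defaults give 441 coefficients per
window. Filters per octave, octave count, order and the log switch are
all configurable via `scattering_config()`.

Design choices worth knowing:

- **Frame normalization.** The bank is normalized so the Littlewood–Paley
  sum $\sum_\lambda |\hat\psi_\lambda|^2 + |\hat\phi|^2$ has maximum 1;
  below the lowest filter center the low-pass is constructed as the exact
  spectral complement, so the sum is flat there. The measured deviation
  over the positive axis is $\delta \approx 0.10$, which gives
  non-expansiveness of the feature map up to that slack (verified on
  random pairs in the tests).
- **FFT implementation with exact envelope decimation.** All convolutions
  are evaluated in the frequency domain. After each modulus, the envelope
  is subsampled by spectral folding — an *exact* subsampling of the
  analytic filter output — to a length matched to the filter bandwidth
  (`decim_margin` envelope samples per bandwidth sigma, default 10). At
  the defaults the whole feature vector agrees with the full-resolution
  computation to ~7×10⁻⁴ relative norm; the classification experiments
  use a faster profile (`decim_margin = 4, decim_margin2 = 2`, ~1.4%
  coefficient deviation), which is far below the feature variability the
  SVM sees after standardization.
- **Boundary handling.** The 90-s window is tapered with 1-s cosine
  ramps before the FFT to suppress periodic wrap-around. The first two
  epochs of each night lack a 60-s history; their windows are left-padded
  by reflecting the head of the recording, and the affected rows carry a
  `padded` flag in the feature table (they are kept in training and
  testing, as clinical epochs would be).

## The synthetic polysomnography generator

The generator (`simulate_hypnogram()`, `simulate_recording()`) stands in
for a private clinical dataset. It produces what the analyses need to be
true of real data, and nothing more:

- **Hypnograms** follow a 5-state Markov chain with persistence 0.85 per
  30-s epoch and redraws from the stationary mix (Awake 27%, REM 9%,
  N1 11%, N2 48%, N3 5% — a typical clinical night's proportions).
- **EEG** is Gaussian noise shaped per stage over five base bands
  (0.5–4, 4–8, 8–15, 15–35, 35–80 Hz) plus a flat 0.05 µV²/Hz floor
  above 80 Hz. Band energies — the quantities every analysis consumes —
  are therefore analytically controllable. REM and N1 have *identical*
  EEG profiles; slow-wave power rises through N2/N3; alpha marks relaxed
  wake. The gamma band (35–80 Hz) is deliberately stage-independent at
  1.2 µV²/Hz: it models genuine high-frequency brain activity whose
  power swamps the leaked muscle signal below 80 Hz, so muscle
  information is usable only above 80 Hz — the interference structure
  seen on real scalp recordings, and the reason a 50 Hz low-pass destroys
  the REM/N1 cue.
- **EMG** is one band-limited (25–250 Hz) unit-variance process scaled by
  a per-stage tone amplitude σ(stage), ordered
  REM < N3 ≤ N2 < N1 < Awake (2, 5, 8, 15, 30 µV): atonia in REM,
  active tone in N1 and wake.
- **Leakage.** The *same* EMG realization, high-pass shaped (4th-order
  Butterworth magnitude, corner 35 Hz) and scaled by a gain `g`
  (default 0.3), is added to every EEG channel. Shared realization is
  what induces the per-epoch EEG–EMG band-energy correlation; the gain
  is the single knob that moves it. At `g = 0.3` the leaked EMG carries
  roughly two thirds of the EEG (80,250) Hz variance in N1, and the
  pooled within-stage log-energy correlation is ≈ 0.6.
- Stage transitions are amplitude cross-faded over 0.5 s to avoid
  spectral splatter at epoch boundaries. All randomness derives from one
  seed; identical (seed, parameters) give bit-identical output.

What the generator does *not* emulate: waveform morphology (spindles,
K-complexes, sawtooth waves), artifacts (electrode pops, sweat, motion),
1/f spectral slopes within bands, apnea physiology, or inter-subject
spectral variability beyond independent noise realizations. Passing
tests on synthetic data therefore demonstrate that the pipeline recovers
the structure the generator encodes — leakage-borne muscle information
above 80 Hz and its benefit for REM/N1 — not that the published
clinical accuracies are reproduced. The printed clinical confusion
matrices are instead verified directly through the metrics module.

## The correlation study

For each EEG channel, six bands ((0.5,15), (15,35), (35,80), (80,150),
(150,250), (80,250) Hz) crossed with six groups (five stages plus All)
give a 36-cell table of pooled Pearson correlations between per-epoch
EEG and EMG log band energies. Significance uses a two-sided permutation
test with the add-one p-value
$p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(1 + n_{perm})$; the analysis
default is 10⁶ permutations, scaled to 10³–10⁴ in tests and scripts.
Flags: `*` when $p < 0.05/36 \approx 0.0014$ (Bonferroni over one
channel's table — the family is per table, not pooled across channels),
`**` when $p < 10^{-5}$. Band energies default to log scale everywhere
(the agreement analyses are defined on log energies); `log = FALSE` is
available, and results must state which scale was used. Bland–Altman
summaries report the (2.5%, 97.5%) empirical quantiles of the per-epoch
log-energy differences, with the linear-interpolation quantile rule
(R type 7).

## Numerical and statistical choices

- **Welch estimator:** 2-s Hamming windows, 50% overlap. 0.5 Hz
  resolution matches the coarsest band edge. Bands are half-open
  `[low, high)`, so (80,150) + (150,250) equals (80,250) exactly on the
  shared grid. Measured stop-band attenuation through this estimator
  saturates near the Hamming sidelobe floor (~43 dB), which bounds what
  the low-pass contract check can observe.
- **CCA:** whitening + SVD with a relative ridge on each view's
  covariance (default 10⁻⁹, effectively exact on well-conditioned views;
  the pipeline uses 10⁻⁴ because scattering features are strongly
  collinear). Signs are fixed by making each direction's
  largest-magnitude first-view loading positive. `k` defaults to
  min(50, view dimension) in the pipeline; the published analysis states
  that CCA reduces dimension but not to what, so k is an explicit
  configuration here.
- **SVM:** `e1071`/libsvm, RBF kernel, one-vs-one. Defaults `C = 10`,
  `gamma = 1/d` on standardized fused features. Subject-grouped 3-fold
  inner tuning over C ∈ {1,10,100} × gamma-scale ∈ {0.3,1,3} is
  implemented (`tune = TRUE`) but off by default: on the synthetic
  cohorts it changes results marginally while multiplying runtime ~25×,
  and fixed defaults keep the five-cohort experiment at desk scale.
  Class weighting (inverse frequency) is always on; whether the original
  analysis standardized, weighted or tuned is not stated anywhere, so all
  three are surfaced as configuration.
- **Zero-denominator conventions:** a class never predicted has
  precision 0; a class absent from truth and prediction has F1 = 0. These
  keep macro F1 total and cannot occur on the printed tables.
- **Rounding for display:** percentages at 2 decimals, kappa at 4,
  per-class table cells as integers rounded half away from zero.

## Problem sizes used by the scripts and tests

Chosen as the package's own desk-scale defaults: the staging experiment
runs 6 subjects × 200 epochs per cohort (the acceptance script runs five
cohorts and reports how often the unfiltered arm wins on REM F1 and
macro F1 together); the correlation study pools 4 subjects × 180 epochs
with 2000 permutations per cell; leakage monotonicity uses one 500-epoch
night per gain in {0, 0.1, 0.3, 1}; permutation-test calibration uses
500 replicates of n = 200 with 10³ permutations. A full-night default
(720 epochs, ~6 h) is available in `simulate_cohort()`.

## Known limitations

- EDF support covers 16-bit continuous EDF/EDF+ with a single sampling
  rate across requested channels; mixed-rate files are rejected rather
  than resampled (resampling would alter the high-frequency content under
  study), and annotations are not parsed (hypnograms travel as CSV).
- The scattering bank uses Gaussian frequency profiles; exact Morlet
  correction terms are omitted (negligible at Q ≥ 1 away from DC, and the
  second-layer width is capped so DC gain stays below 2%).
- The permutation test permutes pairs globally, pooling across subjects
  like the analysis it supports; it does not model within-subject
  dependence of epochs.
- Synthetic results transfer to real data only to the extent the
  generator's assumptions hold (see above); the clinical headline
  numbers are verified from their printed confusion matrices, not
  re-estimated from raw recordings.
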