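# sleephf

Sleep staging from EEG usually throws away everything above ~35 Hz as
noise. But scalp EEG electrodes sit over scalp muscle, and surface EMG —
orders of magnitude larger than EEG and broadband up to several hundred
Hz — leaks into EEG leads above ~35 Hz, most cleanly above 80 Hz. That
leaked activity is a *muscle tone* surrogate, and muscle tone is exactly
what distinguishes the two sleep stages EEG-only scorers confuse most:
REM (muscle atonia) and N1 (tone preserved). `sleephf` is an R package
for studying and exploiting this effect: it quantifies how much EMG
information the high-frequency (80–250 Hz) content of unfiltered 500 Hz
EEG carries, and measures the staging improvement from keeping it.

The package is written for sleep/biosignal researchers. It provides:

- **Signal I/O** — 16-bit EDF reader/writer (µV, single rate;
  mixed-rate channels are rejected, never silently resampled),
  hypnogram CSVs, 30-s epoch segmentation and 90-s context windows.
- **Synthetic polysomnography** — a Markov hypnogram model and a
  stage-dependent spectral EEG/EMG generator with a controllable
  EMG→EEG leakage gain, standing in for private clinical recordings.
- **Features** — an order-2 wavelet scattering transform
  (Morlet-type filters, Q1 = 8, J = 10 octaves, global averaging,
  Rcpp/Armadillo backend) on 90-s windows, plus Welch log band energies
  over (35,80), (80,150), (150,250) Hz.
- **Fusion & classification** — ridge-regularized CCA across two EEG
  channels, RBF-SVM staging, leave-one-subject-out cross-validation
  with strict no-leakage fitting.
- **Evaluation** — 5×5 confusion matrix `M` (rows = expert stage p,
  columns = predicted stage q), per-class precision/recall/F1, overall
  accuracy, Cohen's κ, and Macro F1 = (1/5) Σₚ F1ₚ.
- **Correlation study** — pooled per-stage Pearson correlations of EEG
  vs EMG log band energies, permutation tests (two-sided, add-one
  p-value), Bonferroni flags over the 36-cell per-channel family
  (0.05/36 ≈ 0.0014), and Bland–Altman (2.5%, 97.5%) agreement
  intervals.

## Worked example

Re-deriving every metric of a published filtered-vs-unfiltered staging
comparison from its printed confusion matrices:

```sh
Rscript analysis/04_published_tables.R
```

```
== filtered EEG export (n = 7556 epochs) ==
Overall accuracy: 78.71%
Macro F1:         66.97%
Cohen's kappa:    0.6803
stage    PR   RE   F1
Awake    83   91   87
REM      66   66   66
N1       41   22   29
N2       85   88   86
N3       63   73   67

== unfiltered EEG export (n = 7556 epochs) ==
Overall accuracy: 79.53%
Macro F1:         70.30%
Cohen's kappa:    0.6972
stage    PR   RE   F1
Awake    83   87   85
REM      76   81   78
N1       39   31   34
N2       87   86   87
N3       61   73   67

Gain from keeping >35 Hz content: accuracy +0.82, macro F1 +3.33, kappa +0.0169
REM F1: 66 -> 78; N1 F1: 29 -> 34
```

The numbers to read: keeping the high-frequency content lifts REM F1 by
12 points and N1 F1 by 5 — precisely the two stages muscle tone
disambiguates — while the overall accuracy moves less than one point
(most epochs were never in doubt).

The same experiment end-to-end on synthetic data (simulate a 6-subject
cohort with leakage gain 0.3, run both pipeline arms under LOSOCV,
compare):

```sh
Rscript analysis/03_staging_experiment.R     # ~4 min, writes results/
```

On one such cohort the script reports, among others:

```
High-frequency contribution (unfiltered - filtered):
  accuracy +4.08 points, macro F1 +3.67, kappa +0.0667
  REM F1 +2.55, N1 F1 +10.94
```

— the same direction of change as the clinical comparison above, with the
largest per-class gains again on the muscle-tone stages.

The remaining scripts: `analysis/01_simulate.R` writes a small cohort as
EDF + hypnogram CSV + manifest; `analysis/02_correlation_study.R`
computes the 36-cell EEG–EMG correlation tables and Bland–Altman
intervals on synthetic data — high bands correlate strongly (the
150–250 Hz band most), low bands weakly, reproducing the qualitative
pattern that motivates the whole approach.

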