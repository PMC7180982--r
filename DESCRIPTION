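Package: sleephf
Title: High-Frequency EEG Content as a Muscle-Tone Surrogate for Sleep Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the surface-EMG (muscle tone) information
    carried by the high-frequency (>35 Hz, especially 80-250 Hz) content of
    unfiltered EEG, and for exploiting it in automatic 5-stage sleep scoring
    (Awake/REM/N1/N2/N3). Provides EDF signal input/output, a synthetic
    polysomnography generator with controllable EMG-to-EEG spectral leakage,
    an order-2 wavelet scattering transform for 90-s EEG context windows,
    Welch band-energy features, canonical-correlation fusion of two EEG
    channels, kernel-SVM staging under leave-one-subject-out
    cross-validation, confusion-matrix metrics (accuracy, Cohen's kappa,
    macro F1), and the pooled EEG-EMG band-energy correlation study with
    permutation tests, Bonferroni flags and Bland-Altman summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
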