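Package: pcwave
Title: Trial-Weighted Principal Component Feature Discovery for
    Biomechanical Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pattern-recognition pipeline for ensembles of time-normalized
    biomechanical waveforms from two-group, repeated-trials cohorts.
    Fits a per-variable principal component analysis on a trial-weighted
    correlation matrix (weights equalize subjects with unequal trial
    counts), retains components by Horn's parallel analysis, screens
    principal component scores with a Welch t-statistic cutoff
    (Weiss-Indurkhya independent feature selection), and finds a minimal
    discriminative feature set by consensus over repeated sequential
    forward selection with a cross-validated naive Bayes stopping rule.
    Reports Welch tests and Hedges' g effect sizes for the main features,
    discovers correlated associated features, and produces quartile
    waveform, coefficient-curve and explained-variance artifacts for
    interpretation. Includes a synthetic-cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
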