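Package: zfsleep
Title: Sleep Phenotyping, Arousal Thresholds and Neural Activity Analysis
    for Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying sleep and arousal in larval zebrafish
    from videotracker activity data and trial-structured calcium imaging.
    Implements one-minute sleep scoring with bout, latency and activity
    metrics; variable-slope log-dose psychometric fitting of mechano-acoustic
    tap responses with ETP50 estimation and extra sum-of-squares nested model
    comparison; trial-structured fluorescence (dF/F) quantification with
    phase-window statistics and PCA/ICA neuron segmentation; group-comparison
    statistics (Student's t, ANOVA, Holm-Sidak, Dunnett) and delta-delta-Ct
    expression normalization. A synthetic-data generator with known ground
    truth (two-state Markov behavior, Bernoulli tap responses, transient
    calcium kernels, Gaussian-blob movies) makes the whole pipeline testable
    without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ica,
    minpack.lm,
    mvtnorm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    car,
    knitr
Config/testthat/edition: 3
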