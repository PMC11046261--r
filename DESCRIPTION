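Package: rippleGamma
Title: Ripple Stimuli and Stimulus-Induced Gamma Band-Power Analysis for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of stationary and moving spectrotemporal ripple
    ("auditory grating") stimuli, a synthetic multichannel EEG session
    generator with known injected band-power effects and artifacts, a
    fully automated multi-stage artifact-rejection cascade (impedance,
    fixation breaks, trial RMS bounds, per-frequency PSD outliers,
    electrode/trial consolidation, aperiodic 1/f slope, subject-level
    verdicts), multitaper spectral estimation with baseline-normalized
    band-power change in decibels, and the associated statistical
    comparisons (paired and Welch t tests, Pearson correlation,
    condition-selectivity index, scalp maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
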