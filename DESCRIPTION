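Package: ecogemg
Title: Band-Resolved ECoG and EMG Oscillation Analysis for Longitudinal Rodent Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel electrocorticogram (ECoG) and
    electromyogram (EMG) recordings from longitudinal rodent experiments, such
    as the cerebellar-kainate mouse model of dystonia. Provides Welch power
    spectral density estimation with segment masking, canonical frequency-band
    power extraction (delta through high gamma with a mains-frequency gap),
    magnitude-squared and imaginary cortico-cortical coherence for
    volume-conduction-robust connectivity, EMG amplitude and spectral
    descriptors (RMS, ARV, mean and median frequency over 1-100 Hz),
    behavioral scoring utilities (multi-reviewer dystonia scores, active-wake
    percentages), baseline-percentage normalization across recording days, a
    statistical battery for day-wise comparisons and behavior-signal
    correlations, and a synthetic-cohort generator with fully known ground
    truth for end-to-end parameter-recovery testing. Reads and writes EDF and
    CSV signal files and tidy CSV result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
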