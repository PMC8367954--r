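Package: microstatr
Title: EEG Microstate Segmentation, Temporal Dynamics and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state EEG microstate analysis for developmental cohorts:
    polarity-invariant modified k-means clustering of topographies at global
    field power (GFP) peaks, cluster-number selection by an ensemble
    meta-criterion, two-stage subject-to-group template extraction, winner-takes-all
    back-fitting with a spatial-correlation floor, the four temporal parameters
    (global explained variance, mean duration, time coverage, occurrence),
    Markov-chain transition syntax with occurrence-normalized probabilities,
    normality-gated group comparisons with false discovery rate control,
    clinical correlation analysis, moment-based Welch tests, and bootstrap
    subsampling power curves. Includes a semi-Markov synthetic cohort generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    cluster,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
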