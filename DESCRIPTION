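Package: landemo
Title: EEG-Based Emotion Scoring and Multi-Criteria Evaluation of Village Landscape Scenes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying emotional responses to
    landscape scenes from scene-locked EEG recordings. Computes alpha/beta
    band-power arousal and frontal-asymmetry valence indices from raw or
    pre-computed band powers, ranks scenes with an integrated grey relational
    analysis and VIKOR compromise model under entropy weights, diagnoses
    per-scene obstacle factors, and estimates dose-response thresholds
    (linear slopes, step effects, optimal intervals) of landscape indicators
    on emotion with false-discovery-rate control. Includes a fully seeded
    synthetic-data module with known latent emotion structure so every stage
    is testable without access to field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
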