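Package: gazeforage
Title: Eye and Head Movement Analysis for Immersive Foraging Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synchronized eye and head rotation streams
    recorded during head-mounted-display visual foraging tasks. Provides a
    synthetic session generator with ground-truth events, validity handling and
    gap interpolation, timebase alignment, velocity-threshold saccade detection
    with an adaptive elliptical threshold, sliding-window head-movement
    classification, a 76-feature trial-level battery of fixation, saccade,
    coordination and kinematic measures, signal-detection behavioural measures,
    and a classification suite (shadow-feature selection, RBF support vector
    machines under stratified cross-validation, exact Wilcoxon comparisons with
    Holm correction and Hedges' g, and Shapley-style feature ranking) for
    decoding task condition from movement features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    e1071,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
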