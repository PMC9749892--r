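Package: crylight
Title: Circadian Locomotor, Light-Evoked Electrophysiology, and Light-Choice
    Assay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for four standard assays used to characterize
    Cryptochrome-dependent light responses in flies: chi-square
    (Sokolove-Bushell) periodogram analysis of locomotor activity with
    FaasX-style rhythmicity criteria and LD anticipation indices; whole-cell
    current-clamp light-response analysis (spike detection,
    firing-frequency ratios, tonic/burst classification, and sweep-averaged
    low-pass-filtered evoked potentials); two-environment light
    attraction/avoidance preference; and background-normalized ROI
    fluorescence profiles across Zeitgeber time.  A statistics layer
    implements normality-dispatched two-group tests with Benjamini-Hochberg
    FDR adjustment and two-tier significance labeling.  Seed-reproducible
    synthetic-data generators emulate each assay so every stage can be
    verified by parameter recovery without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    rlang,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
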