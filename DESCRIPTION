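Package: actiscreen
Title: Multi-Night Actigraphy Screening for Chronic Insomnia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated pre-screening of chronic insomnia from multi-night
    wrist-actigraphy recordings. Applies a wake-sensitivity intensity-filter
    bank to per-minute activity counts, extracts 48 night-level features
    (statistical moments, Poincare plot descriptors including the complex
    correlation measure, sample entropy, and rule-based sleep parameters),
    and classifies subjects with a two-layer model: night-level good/bad
    prediction under leave-one-subject-out cross-validation followed by a
    learned bad-night-count threshold. Includes a seeded synthetic cohort
    generator, per-feature Mann-Whitney/AUC statistics, threshold sweeps,
    night-count ablation and random-label controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    e1071,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
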