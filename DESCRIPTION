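Package: cilffa
Title: Chemical Isotope Labeling LC-MS Analysis of Free Fatty Acids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end processing of chemical-isotope-labeling (CIL)
    LC-MS feature data for free fatty acid (FFA) profiling: exact
    monoisotopic mass arithmetic for light/heavy amide derivatives
    (DMED and d4-DMED), de novo CHNO molecular-formula generation from
    accurate mass, retention-index calibration from a labeled
    alkanoic-acid ladder, light/heavy peak-pair extraction, library and
    formula annotation, internal-standard relative quantitation with
    sample QC, presence/absence comparison across tissue regions, and
    feature selection by one-way ANOVA combined with OPLS-DA variable
    importance. Includes a fully deterministic synthetic-data generator
    with ground-truth manifests so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
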