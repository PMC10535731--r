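Package: radsyn
Title: Drug-Radiation Synergy Scoring for Preclinical Combination Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for scoring drug-radiation synergy in
    preclinical studies: alamarBlue viability curves and IC50 estimation,
    clonogenic surviving fractions with Bliss-multiplicativity
    classification, linear-quadratic survival fitting, tumor growth delay
    and volume-based combination-index analysis from caliper measurements,
    and immune/toxicity cohort summaries (spleen indices, lymphocyte
    subsets, tiered significance annotation, biochemistry reference-range
    flags). Includes seedable synthetic-data generators that emulate each
    assay with known ground truth for calibration and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
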