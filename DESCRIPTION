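Package: paintqc
Title: Quality Control and Reproducibility Metrics for Cell Painting Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end processing and quality control of Cell Painting
    morphological profiles from high-content screens: single-cell cleaning
    with a histogram-based outlier score (HBOS), median aggregation to
    well-level profiles, plate-wise robust normalization against DMSO
    negative controls, staged feature selection, consensus profiles over
    replicates, compound toxicity and induction (activity) filtering,
    permutation-null reproducibility metrics (percent replicating, percent
    matching, percent pairing), plate heatmap QC matrices, and dead-cell and
    senescence readouts. Includes a synthetic plate generator that emulates
    the statistical structure of 384-well Cell Painting screens so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
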