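Package: crequant
Title: Whole-Brain Expression Energy Quantification for Transgenic Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable informatics pipeline for characterizing
    transgenic (Cre driver) mouse lines from serial in situ hybridization
    (ISH) section images. Provides a toy hierarchical brain ontology and
    annotation volume emulating a reference atlas, a synthetic-histology
    generator (Poisson cell placement, serial 25 um sectioning every 200 um),
    robust expression-mask segmentation, 200 um gridding with atlas structure
    assignment, the per-structure "expression energy" statistic, and the
    downstream statistics used to compare Cre reporter and endogenous gene
    expression profiles: plane-matched replicate-averaged Spearman
    correlations, percentile binning, fold-change enrichment ranking, and
    two-tailed t-test group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    tiff,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
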