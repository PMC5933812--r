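Package: introscan
Title: Supervised Detection of Introgressed Genomic Windows from
    Two-Population Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies genomic windows from two related population samples
    as introgressed (in either direction) or not, using an extremely
    randomized trees classifier trained on coalescent simulations. Computes
    a 31-statistic feature vector per window (within-population diversity,
    site-frequency and linkage-disequilibrium summaries, and
    cross-population divergence statistics including d_min, G_min, d_d and
    Z_X), simulates labelled training and test data under two-population
    isolation models with pulse or continuous migration and migrant-truth
    tracking, and provides genome scanning, region clustering, refinement,
    permutation enrichment, and ROC/power evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ranger,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    withr
SystemRequirements: python (>= 3.8) with msprime (>= 1.0) and numpy, for
    the coalescent simulation module
Config/testthat/edition: 3
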