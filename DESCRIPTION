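Package: raceblend
Title: Cross-Population Comparison of Somatic Mutation Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for comparing somatic mutation frequencies between
    patient populations while controlling for technical and biological
    confounders. Provides per-exon read-depth harmonization by binomial
    downsampling with consensus mutation calling, propensity-score
    matching-weight adjustment of clinical covariates with a weighted
    chi-squared test for population-biased mutated genes (with
    Benjamini-Hochberg false discovery rate control and label-permutation
    validation), Hudson's Fst estimator and genotype-based sample
    clustering, and companion mutual-exclusivity, Kaplan-Meier/log-rank
    survival and paired signed-rank association tests. A synthetic
    three-cohort generator with configurable confounding, depth asymmetry
    and a coupled germline variant makes every stage testable without
    access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
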