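Package: methgene
Title: Gene-Based Tests of Methylation-Moderated SNP Effects on a
    Quantitative Trait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage gene-based association testing for quantitative
    traits where SNP effects are moderated by the methylation level of a
    nearby CpG site. Stage one residualizes the trait on covariates and a
    pedigree-derived kinship random effect (REML via a single
    eigendecomposition); stage two fits a per-pair regression of the
    residuals on SNP, CpG and their interaction and records the overall
    F-test p-value. Per-gene evidence is combined with six p-value
    combiners (Fisher-type sum of log p, sum of negative squared log p,
    minimum p, and three truncated threshold statistics) whose
    significance is assessed by a shared-shuffle residual-permutation
    engine. Includes quality-control filtering, nearest-CpG pairing,
    gene/set assembly, a family-based synthetic cohort generator with
    heritability-calibrated SNP-by-CpG effects, and an experiment harness
    that tabulates type-I error and power over replicate cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
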