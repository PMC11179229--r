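Package: mtgwas
Title: Multi-Trait Mixed-Model GWAS with Factor-Analytic Trait Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of designed plant-breeding trials and
    multi-trait genome-wide association scans for inbred panels. Stage one
    fits single-trait mixed models for lattice, randomized complete block
    and augmented designs, returning REML variance components, adjusted
    line means (BLUEs), BLUPs with prediction error variances and Cullis
    generalized heritabilities. Stage two fits a no-marker multi-trait
    mixed model with Kronecker covariance (VanRaden genomic relationship
    by factor-analytic or unstructured trait covariance, chosen by AIC),
    scans SNPs by generalized least squares with leave-one-chromosome-out
    kinship, refits hits under full REML with Wald tests, and reports
    effect confidence intervals, favorable alleles and variance explained.
    Includes linkage-disequilibrium characterization (squared genotypic
    correlations with Fisher exact tests) and a synthetic-data generator
    for inbred genotype panels, pleiotropic QTL architectures and
    plot-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
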