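Package: metsel
Title: Multi-Environment Trial Analysis, Selection Indices, and Association
    Mapping for Seed Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-environment trials of seed traits in
    inbred crop panels. Provides balanced genotype-by-location ANOVA with
    method-of-moments variance components and broad-sense heritability,
    Smith-Hazel optimum selection indices with cross-location selection,
    GGE (genotype plus genotype-by-environment) biplots via singular value
    decomposition, and a genome-wide association stage with general linear,
    mixed linear (P3D), and FarmCPU-style iterative models, kinship and
    principal-component covariates, suggestive 1/N significance thresholds,
    per-SNP effect sizes, and linkage-disequilibrium follow-up. A synthetic
    data generator with Balding-Nichols population structure and planted
    QTLs emulates the statistical structure of such trials so that every
    stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
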