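Package: dyadGWAS
Title: Case-Control GWAS and Maternal-Fetal Dyad Analysis for Placental Abruption Genetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for case-control genetic association studies
    of pregnancy outcomes with mother-child (maternal-placental) duo data.
    Provides PLINK-style PED/MAP input and output, genotype quality control
    (call rate, minor allele frequency, Hardy-Weinberg exact test), per-SNP
    logistic association scans with principal-component adjustment,
    Benjamini-Hochberg false discovery rate control and genomic inflation
    estimates, penalized SNP selection (lasso with cross-validated penalty and
    linkage-disequilibrium expansion; composite minimax concave penalty for
    bi-level gene/SNP selection), repeated cross-validated weighted genetic
    risk scores with quartile odds ratios and AUC, and a multinomial likelihood
    for mother-child genotype duos with maternal, fetal, interaction and
    parent-of-origin imprinting effects selected by BIC and tested by
    likelihood ratio. A seeded synthetic-data generator emulates the assumed
    data structure so every stage is testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
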