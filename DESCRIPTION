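Package: epiPRS
Title: Gene-Gene Interaction Polygenic Risk Scores and Gene-Lifestyle
    Interaction Analysis for COPD Case-Control Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for epistasis-informed polygenic risk
    score (PRS) analysis of chronic obstructive pulmonary disease (COPD)
    in population cohorts: covariate-adjusted single-SNP logistic
    screening with Hardy-Weinberg exact tests and genomic-control lambda,
    D-prime linkage-disequilibrium pruning via EM haplotype-frequency
    estimation, generalized multifactor dimensionality reduction (GMDR)
    epistasis model search with cross-validation consistency and sign
    tests, unweighted risk-allele PRS construction with Low/Middle/High
    categorization, and PRS-by-lifestyle interaction and stratified
    odds-ratio analysis. Includes a synthetic-cohort generator that
    reproduces the statistical structure of a Korean population-based
    COPD study (Hardy-Weinberg genotypes at published minor-allele
    frequencies, prevalence-calibrated logistic disease models, planted
    epistasis, and gene-lifestyle interactions) so the whole chain runs
    and can be validated without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    emmeans,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
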