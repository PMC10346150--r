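# epiPRS

Epistasis-informed polygenic risk scores (PRS) and gene–lifestyle
interaction analysis for COPD case-control cohorts.

## The problem

Chronic obstructive pulmonary disease (COPD) — persistent airflow
limitation, diagnosed spirometrically as FEV1/FVC < 0.7 — has a
polygenic heritable component whose variants act jointly rather than
alone, and whose combined burden interacts with modifiable exposures
(omega-3 fatty-acid intake, exercise). epiPRS is for epidemiologists and
statistical geneticists who want to run that full analysis on a
population cohort with genotypes, spirometry, covariates and lifestyle
data:

1. **Screen**: per-variant additive logistic regression of case status
   on minor-allele dosage + covariates, after QC (missing-call rate
   ≥ 4% and Hardy–Weinberg exact p < 0.05 excluded); candidates at
   p < 5×10⁻⁵; genomic-control λ.
2. **Prune**: pairwise |D′| from EM haplotype frequencies; of any
   candidate pair with |D′| ≥ 0.2 the smaller-p member is kept.
3. **GMDR**: generalized multifactor dimensionality reduction —
   covariate-adjusted score residuals *s = y − p̂*, 3^k genotype cells
   labeled high/low risk by their training score sum, exhaustive subset
   search under 10-fold stratified cross-validation, reporting trained /
   test balanced accuracy (TRBA/TEBA), cross-validation consistency
   (CVC) and an exact sign test; models pass at sign p < 0.001 and
   CVC = 10/10.
4. **PRS**: unweighted risk-allele count over the selected SNPs (risk
   allele = minor if scan OR > 1, else major), categorized Low/Middle/
   High (five-SNP model cutoffs ≤4 / 5–6 / ≥7); adjusted category odds
   ratios with the Low group as reference.
5. **G×E**: PRS-trend × dichotomized-exposure interaction in a logistic
   model; stratified category ORs and Tukey-compared adjusted means of
   FEV1/FVC after a significant interaction.

Because the motivating cohort (a Korean population study, n = 8840,
875 COPD cases, 9.9% prevalence) is access-restricted, the package
includes a synthetic-cohort generator whose defaults reproduce that
study's statistical structure — HWE genotypes at the published
minor-allele frequencies, published per-allele odds ratios,
prevalence-calibrated logistic disease models, planted epistasis and
stratum-specific gene–lifestyle effects — so the whole chain runs and
is validated end to end with ground truth.

## Worked example

```r
library(epiPRS)

ce <- simulateCohort(simulationConfig(nSamples = 8840), seed = 7)
ce
#> CohortExperiment: 8840 samples x 10 variants
#>   COPD cases: 880 (10.0%)
#>   simulated cohort with ground truth (see groundTruth())

qc   <- qcFilter(ce)
scan <- logisticScan(qc$cohort, covariateSet("gwas"))
head(scan[, c("id", "or_adj", "se", "p", "maf", "hwe_p")], 3)
#>            id or_adj     se        p    maf hwe_p
#> 1 rs117262613  2.292 0.1628 3.48e-07 0.0139 0.689
#> 2   rs1585258  0.838 0.0523 7.21e-04 0.4286 0.350
#> 3    rs889294  1.327 0.0520 5.66e-08 0.3296 0.220
```

Each scan row is a variant's covariate-adjusted per-minor-allele odds
ratio with Wald SE and p; `maf` and `hwe_p` are the sample minor-allele
frequency and Hardy–Weinberg exact p. Variant rs1585258 (FAM13A) is
protective (OR < 1), so its *major* allele counts toward the PRS:

```r
rmap <- riskAlleleMap(scan, fiveSnpModel())
prof <- computePrs(qc$cohort, rmap, cutoffs = c(4, 7))
table(prof$category)
#>    low middle   high
#>   6964   1709    167

adjustedCategoryOr(phenotypes(ce), prof$category, covariateSet("set1"))
#>   category    n n_cases   or ci_lo ci_hi        p flagged
#> 1      low 6964     612 1.00    NA    NA       NA   FALSE
#> 2   middle 1709     233 1.66  1.41  1.96 8.59e-10   FALSE
#> 3     high  167      35 2.79  1.90  4.11 1.90e-07   FALSE
```

High-PRS participants carry a 2.8-fold (95% CI 1.9–4.1) higher adjusted
odds of COPD than Low-PRS in this simulated cohort (the generating
per-allele effects are the published ones, so the exact value varies by
seed). The whole chain — simulate → QC/scan → prune → GMDR → PRS → G×E —
runs as one reproducible command:

```r
runPipeline(pipelineConfig(), outDir = "copd_run", seed = 1)
```

which writes `assoc.tsv`, `ld_pairs.tsv`, `gmdr_models.tsv`,
`prs_or.tsv`, `interaction.tsv`, `stratified_or.tsv`,
`adjusted_means.tsv` and a `manifest.json` of file hashes (bit-identical
on rerun). See `vignettes/epiPRS-methods.Rmd` for the model details and
design choices.

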