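---
title: "Methods: epistasis-informed polygenic risk scores for COPD"
author: "epiPRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epistasis-informed polygenic risk scores for COPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiPRS)
```

## The analysis this package implements

Chronic obstructive pulmonary disease (COPD) is diagnosed spirometrically
by a forced expiratory volume (FEV1) to forced vital capacity (FVC) ratio
below 0.7. Its heritable component is polygenic, and individual variants
identified in genome-wide screens rarely act alone: variants in
lung-structure genes (FAM13A, CAV1, CPD, PEPD, ITGA1, ...) appear to act
jointly, and their combined burden interacts with modifiable exposures
such as omega-3 fatty-acid intake and exercise. epiPRS packages that full
analysis chain for case-control cohorts with genotype, spirometry and
lifestyle data:

1. **Single-SNP screen** (`qcFilter()`, `logisticScan()`): variant QC
   (missing-call rate >= 4% excluded, Hardy-Weinberg exact p < 0.05
   excluded), then a per-variant additive logistic regression of case
   status on minor-allele dosage plus covariates. Candidates are the
   variants with p < 5e-5 (`selectCandidates()`), and `genomicLambda()`
   reports the median-based genomic-control inflation factor.
2. **Redundancy pruning** (`emHaplotypeFreqs()`, `dPrime()`,
   `ldPrune()`): pairwise |D'| between candidates, estimated by EM over
   the phase-ambiguous double-heterozygote class; of any pair with
   |D'| >= 0.2 the better-powered member (smaller scan p) is retained.
   *Note*: the analysis convention we follow is stated elsewhere in the
   self-contradictory form "high LD (D' < 0.2) excluded"; the only
   reading consistent with removing redundancy is the one implemented —
   exclude one of each pair in high LD, keep independent variants.
3. **GMDR epistasis search** (`gmdrSearch()`): generalized multifactor
   dimensionality reduction. Per-sample scores are the residuals
   y − p̂ from the covariate-only logistic model (`scoreStatistics()`),
   so covariate effects are removed before any genotype pattern is
   examined. For a k-SNP subset, each of the 3^k genotype cells is
   labeled high-risk if its training score sum is positive, low
   otherwise. A 10-fold cross-validation stratified by case status
   evaluates every subset per fold: the subset maximizing trained
   balanced accuracy (TRBA) is chosen and test balanced accuracy (TEBA)
   is measured on the held-out fold. Models are summarized by
   cross-validation consistency (CVC: folds choosing the modal subset)
   and a one-sided exact sign test on folds with TEBA > 0.5.
   `selectBestModel()` defaults to the stricter reporting criteria
   (sign p < 0.001 and CVC = 10/10); the screening pair (p < 0.05,
   CVC >= 9) is available.
4. **Risk-allele PRS** (`riskAlleleMap()`, `computePrs()`,
   `prsCategory()`): the PRS is the unweighted count of risk alleles
   across the selected SNPs; the risk allele is the minor allele when
   the scan OR exceeds 1 and the major allele otherwise. For the
   five-SNP model the published category cutoffs are <=4 (Low), 5–6
   (Middle), >=7 (High).
5. **PRS-lifestyle interaction** (`interactionTest()`,
   `stratifiedOr()`, `adjustedMeans()`): a logistic model with an
   ordinal PRS trend (0/1/2), the dichotomized exposure, their product
   and covariates; upon a significant product term, category odds
   ratios are re-estimated within each exposure stratum, and adjusted
   means of FEV1/FVC by group are compared with Tukey-adjusted
   pairwise tests (via `emmeans`).

`runPipeline()` chains all stages with one master seed, writing every
table and a hash manifest so reruns are bit-identical.

## Key parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `maxMissingRate` | 0.04 | missing-call fraction at/above which a variant is dropped |
| `hweAlpha` | 0.05 | HWE exact p below which a variant is dropped (strictly below) |
| `pCandidate` | 5e-5 | screen threshold (strictly below) |
| `dPrimeThreshold` | 0.2 | \|D'\| at/above which a candidate pair is redundant |
| `signAlpha`, `minCvc` | 0.001, 10 | GMDR model-selection criteria |
| `prsCutoffs` | (4, 7) | Low/Middle/High boundaries for a five-SNP PRS |
| lifestyle cutoffs | `lifestyleCutoffs()` | reference intakes; value >= cutoff is "high" (ties high, since cutoffs are attained recommended intakes) |

Case definition (`defineCopdStatus()`): the default `spirometry_or_dx`
rule calls a participant a case when FEV1/FVC < 0.7 *or* a physician
previously diagnosed COPD; the pure spirometric rule is selectable. The
source analyses describe both readings; the disjunction matches the
stated inclusion of undiagnosed low-ratio participants.

Boundary conventions, chosen once and tested: missingness >= 4%
excludes; HWE and candidate thresholds are strict `<`; minor-allele ties
at frequency 0.5 resolve to the alphabetically first allele; GMDR cell
score ties label the cell low-risk; unseen/empty cells predict low risk;
TRBA ties break lexicographically; TEBA ties in model selection go to
the smaller k.

## The synthetic-cohort generator

Real cohort data of this kind (the Korean population study the analysis
is modeled on, n = 8840, 875 cases) are access-restricted, so the
package ships a generator (`simulateCohort()`) whose defaults *are* the
study conditions:

* **Genotypes**: independent Binomial(2, MAF) columns — Hardy-Weinberg
  by construction — at the published MAFs of the ten-variant candidate
  panel (`studyVariants()`).
* **Disease model**: logistic, combining per-minor-allele log-ORs
  (defaults: the published adjusted ORs), covariate effects, an optional
  planted 3^k-cell epistasis offset table, and an optional PRS-category
  / stratum-specific gene-lifestyle term. The intercept is calibrated by
  monotone root finding (`calibrateIntercept()`) so the expected case
  fraction over the realized cohort equals the 9.9% target exactly.
* **Covariates**: age ~ Normal(52, 8) truncated to 40–69, 47% male,
  BMI ~ Normal(24.6, 3), 53% city residence, smoking 60/15.5/24.5%
  never/former/current, and nutrient/lifestyle marginals echoing the
  published cohort tables; the joint distribution is independent because
  no joint information is published. Covariate effect defaults (per-year
  age log-OR 0.04, male log(1.503), city log(0.786), BMI −0.03) echo the
  published adjusted associations.
* **Spirometry**: in the default mode the FEV1/FVC ratio is drawn
  conditionally on case status (cases below 0.7, controls at/above), so
  `defineCopdStatus()` reproduces the simulated status exactly; the
  `"ratio"` mode instead makes the ratio additive in risk alleles
  (steeper slope in the low-exposure stratum) and derives case status
  from it.
* **LD**: `simulateLDPair()` samples haplotype pairs from a specified
  2x2 haplotype table, giving exact control of D' for testing the
  pruning stage.

What the generator does *not* emulate: genomic-scale variant counts
(candidate-panel scale only), population structure and relatedness,
linkage beyond requested pairs, genotyping error, informative
missingness, and the real correlation structure among diet, exercise and
smoking. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated statistical structure, not robustness to
real-data artifacts.

## Numerical choices

* Logistic fits use `stats::glm.fit` (IRLS maximum likelihood) with Wald
  standard errors from the QR decomposition, matching the Wald-interval
  convention of the original SAS analyses. Non-convergence and
  (quasi-)separation are flagged and the p-value withheld rather than
  reported.
* The HWE exact test enumerates heterozygote counts with the standard
  probability-ratio recurrence; the test suite checks it exhaustively
  against an independent closed-form enumeration for every table of up
  to 50 individuals.
* EM for haplotype frequencies starts at linkage equilibrium, iterates
  to Δlog-likelihood < 1e-10 (max 1000 iterations), and asserts the
  log-likelihood never decreases.
* Intercept calibration brackets and bisects to 1e-10 on the prevalence
  scale (limit 200 iterations).
* Averages of odds-ratio estimates across simulation replicates are
  geometric means (means of log-ORs), the natural scale for ratio
  estimates.

## Known limitations

* |D'| is upward-biased in small samples, drastically so for rare
  variants: at n in the low thousands, variants with MAF ~0.01 show
  chance |D'| >= 0.2 against unlinked common variants in a third of
  replicates. The published 0.2 threshold is therefore aggressive at
  small n; the pipeline examples use common variants.
* With the published MAFs and cutoffs, the High-PRS category holds only
  ~1.8% of an HWE cohort, so stratified high-vs-low odds ratios rest on
  few events (~15 per stratum at n = 8840, 9.9% prevalence). Replicate
  averages of such estimates carry a few percent of small-sample bias —
  visible in the stratified-recovery checks — and single-cohort
  estimates have wide intervals; the small-stratum flag on
  `stratifiedOr()` marks the worst cases.
* The GMDR search is exhaustive per k; its cost is C(m, k) x folds, so
  candidate lists should be pruned below ~20 before k = 5.
* No weighted PRS, no multiple-testing correction across exposure rows,
  no mixed-model stratification control — all deliberately out of
  scope, mirroring the analysis the package operationalizes.

## Problem sizes used in the shipped checks

Unit and property tests run on cohorts of 50–20,000 samples. The
recovery checks in the test suite use 25–50 replicate cohorts of
n = 4000–8840 and compare replicate means within two Monte-Carlo
standard errors; the standalone `scripts/acceptance.R` runs the same
recoveries at 200 replicates of n = 8840. The GMDR oracle-equivalence
property is exercised exhaustively for up to 6 candidates, k <= 3,
n <= 200, and the exhaustive HWE comparison covers all genotype tables
of up to 50 individuals.
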