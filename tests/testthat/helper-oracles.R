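# Independent oracles and small fixture builders used across the suite.

# Hardy-Weinberg exact p by direct enumeration over heterozygote counts,
# using the closed-form multinomial/hypergeometric probability (a code
# path independent of the package's ratio recurrence).
oracleHwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  r <- min(2 * nAA + nAa, 2 * naa + nAa)
  if (r == 0) return(1)
  hs <- seq(r %% 2, r, by = 2)
  lp <- vapply(hs, function(h) {
    a <- (r - h) / 2
    b <- n - h - a
    lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(h) +
      h * log(2) + lfactorial(r) + lfactorial(2 * n - r) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[hs == nAa]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# Naive GMDR cross-validation: string-keyed cells, tapply score sums,
# per-fold exhaustive subset evaluation. Independent of the package's
# base-3 coding and tabulation.
oracleGmdrFold <- function(dosage, y, scores, candidates, k, folds, f) {
  subsets <- combn(candidates, k, simplify = FALSE)
  train <- which(folds != f)
  test <- which(folds == f)
  ba_of <- function(s, idx, high) {
    key <- apply(dosage[idx, s, drop = FALSE], 1, paste, collapse = "-")
    pred <- key %in% high
    yi <- y[idx]
    (mean(pred[yi]) + mean(!pred[!yi])) / 2
  }
  highCells <- function(s) {
    key <- apply(dosage[train, s, drop = FALSE], 1, paste,
                 collapse = "-")
    sums <- tapply(scores[train], key, sum)
    names(sums)[sums > 0]
  }
  bas <- vapply(subsets, function(s) ba_of(s, train, highCells(s)),
                numeric(1))
  best <- which.max(bas)
  s <- subsets[[best]]
  list(snps = paste(s, collapse = ","), trba = bas[best],
       teba = ba_of(s, test, highCells(s)))
}

# write a small VCF 4.2 text file; gts is a variants x samples character
# matrix of GT strings
writeToyVcf <- function(path, chrom, pos, id, ref, alt, gts, samples) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  for (i in seq_along(pos))
    writeLines(paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".",
                       "PASS", ".", "GT", gts[i, ]), collapse = "\t"),
               con)
  close(con)
  path
}

# minimal cohort from a dosage matrix and optional phenotype columns
toyCohort <- function(dosage, ...) {
  m <- ncol(dosage)
  vi <- data.frame(id = colnames(dosage),
                   chromosome = as.character(seq_len(m)),
                   position = seq_len(m) * 100L,
                   minor_allele = rep("A", m),
                   major_allele = rep("G", m),
                   stringsAsFactors = FALSE)
  ph <- data.frame(sample_id = rownames(dosage), ...,
                   stringsAsFactors = FALSE)
  CohortExperiment(dosage, vi, ph)
}

# single-SNP case-control cohort drawn from a prevalence-calibrated
# logistic model; returns the cohort only (used by recovery checks)
simulateSingleSnpCohort <- function(maf, or, n, prevalence, seed) {
  withr::with_seed(seed, {
    g <- simulateGenotypes(maf, n)
    eta <- log(or) * g
    b0 <- calibrateIntercept(eta, prevalence)
    y <- runif(n) < plogis(b0 + eta)
  })
  d <- matrix(as.integer(g), ncol = 1,
              dimnames = list(sprintf("s%05d", seq_len(n)), "snp1"))
  toyCohort(d, copd = y)
}

# five-SNP PRS-category simulation config at the published MAFs with the
# given category log-ORs (optionally stratum-specific via gxe)
fiveSnpPrsConfig <- function(n, logOrMid, logOrHigh, gxe = NULL) {
  sv <- studyVariants()
  five <- fiveSnpModel()
  vars <- data.frame(id = five, maf = sv$maf[match(five, sv$id)],
                     log_or = 0)
  risk <- ifelse(sv$or_adj[match(five, sv$id)] > 1, "minor", "major")
  pe <- list(snps = five, riskAlleles = risk, lowMax = 4, highMin = 7)
  if (is.null(gxe)) {
    pe$logOrMid <- logOrMid
    pe$logOrHigh <- logOrHigh
  }
  simulationConfig(nSamples = n, variants = vars, prsEffect = pe,
                   gxe = gxe)
}

# scan-like table whose or_adj directions reproduce the published risk
# alleles of the five-SNP model
fiveSnpRiskMap <- function() {
  sv <- studyVariants()
  five <- fiveSnpModel()
  riskAlleleMap(data.frame(id = five,
                           or_adj = sv$or_adj[match(five, sv$id)]),
                five)
}

geoMeanSummary <- function(ors) {
  lo <- log(ors)
  lo <- lo[is.finite(lo)]
  list(mean = exp(mean(lo)), se_log = sd(lo) / sqrt(length(lo)),
       mean_log = mean(lo), n = length(lo))
}
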