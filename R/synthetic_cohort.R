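#' The ten-variant COPD candidate panel
#'
#' The published characteristics of the ten COPD-associated variants from
#' the Korean Ansan/Ansung population cohort that this package's analyses
#' are modeled on: identifier, location, minor/major allele, adjusted
#' per-minor-allele odds ratio with its standard error and p-value, minor
#' allele frequency and Hardy-Weinberg p. These printed values are the
#' default generating parameters of [simulationConfig()].
#'
#' @return `data.frame`, one row per variant.
#' @export
studyVariants <- function() {
  data.frame(
    id = c("rs117262613", "rs1585258", "rs889294", "rs4145714",
           "rs1997571", "rs10959052", "rs74433025", "rs719601",
           "rs17482826", "rs17569"),
    chromosome = c("3", "4", "5", "7", "7", "9", "11", "17", "18", "19"),
    position = c(21603388L, 89879196L, 52110676L, 48391642L, 116198621L,
                 10332654L, 132172642L, 28731415L, 8796149L, 33882222L),
    minor_allele = c("A", "G", "A", "C", "G", "C", "C", "G", "T", "A"),
    major_allele = c("G", "T", "G", "G", "A", "T", "T", "A", "A", "G"),
    or_adj = c(2.209, 0.7895, 1.281, 0.7009, 1.269, 0.7293, 2.156,
               1.28, 2.304, 1.251),
    se = c(0.1958, 0.0588, 0.0593, 0.0808, 0.0598, 0.0856, 0.1968,
           0.0663, 0.1676, 0.0636),
    p = c(5.16e-6, 5.74e-6, 2.96e-5, 6.68e-7, 4.96e-5, 5.45e-7,
          9.51e-6, 2.12e-5, 6.41e-7, 4.35e-5),
    maf = c(0.0134, 0.4271, 0.3251, 0.3653, 0.3372, 0.1456, 0.0140,
            0.2168, 0.0742, 0.2433),
    hwe_p = c(0.207, 1.0, 0.191, 0.277, 0.175, 0.266, 1.0, 0.778,
              0.315, 0.112),
    gene = c("ZNF385D", "FAM13A", "ITGA1", "ABCA13", "CAV1", "PTPRD",
             "NTM", "CPD", "MTCL1", "PEPD"),
    stringsAsFactors = FALSE)
}

#' SNPs of the five-variant epistasis PRS model
#'
#' The five lung-function genes of the reported best SNP-SNP interaction
#' model, with the risk allele implied by the direction of each variant's
#' adjusted odds ratio (minor allele when OR > 1, major allele otherwise).
#'
#' @return character vector of five variant ids.
#' @export
fiveSnpModel <- function() {
  c("rs1585258", "rs1997571", "rs719601", "rs17569", "rs889294")
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are drawn `Binomial(2, maf)` independently per sample, which is
#' Hardy-Weinberg equilibrium by construction.
#'
#' @param maf minor-allele frequency in `[0, 0.5]`.
#' @param n number of samples.
#' @return integer vector of dosages 0/1/2.
#' @examples
#' table(simulateGenotypes(0.3, 1000))
#' @export
simulateGenotypes <- function(maf, n) {
  if (!is.finite(maf) || maf < 0 || maf > 0.5)
    stop("maf must lie in [0, 0.5], got ", maf)
  rbinom(n, 2L, maf)
}

#' Simulate an LD pair by haplotype sampling
#'
#' Draws two haplotypes per individual from a specified two-locus
#' haplotype frequency table, giving exact control of D-prime. Haplotype
#' frequencies are ordered (minor-minor, minor-major, major-minor,
#' major-major).
#'
#' @param hapFreqs numeric(4) summing to 1.
#' @param n number of individuals.
#' @return integer matrix `n x 2` of minor-allele dosages.
#' @export
simulateLDPair <- function(hapFreqs, n) {
  stopifnot(length(hapFreqs) == 4, abs(sum(hapFreqs) - 1) < 1e-8,
            all(hapFreqs >= 0))
  hap <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = hapFreqs),
                ncol = 2)
  # haplotypes 1,2 carry the minor allele at locus 1; 1,3 at locus 2
  cbind(rowSums(hap <= 2), rowSums(hap == 1 | hap == 3))
}

#' Calibrate the disease-model intercept to a target prevalence
#'
#' Finds the intercept `b0` such that the expected case fraction
#' `mean(plogis(b0 + eta))` over the supplied linear-predictor
#' distribution equals the target prevalence. The expectation is monotone
#' in `b0`, so the root is found by bracket expansion and bisection.
#'
#' @param eta numeric vector of linear-predictor contributions excluding
#'   the intercept (one entry per sample or per cell of a discrete
#'   distribution).
#' @param target target prevalence in (0, 1).
#' @param weights optional probability weights for `eta` (cell
#'   probabilities); default equal weight.
#' @param tol convergence tolerance on the prevalence scale.
#' @param maxIter maximum bracket/bisection iterations.
#' @return the intercept (log-odds scale).
#' @examples
#' calibrateIntercept(0, 0.099)  # qlogis(0.099)
#' @export
calibrateIntercept <- function(eta, target, weights = NULL, tol = 1e-10,
                               maxIter = 200) {
  stopifnot(all(is.finite(eta)), target > 0, target < 1)
  if (is.null(weights)) weights <- rep(1 / length(eta), length(eta))
  weights <- weights / sum(weights)
  f <- function(b0) sum(weights * plogis(b0 + eta)) - target
  lo <- qlogis(target) - max(abs(eta)) - 1
  hi <- qlogis(target) + max(abs(eta)) + 1
  it <- 0
  while (f(lo) > 0) { lo <- lo - 5; it <- it + 1
    if (it > maxIter) stop("intercept bracket failed: lo=", lo) }
  while (f(hi) < 0) { hi <- hi + 5; it <- it + 1
    if (it > maxIter) stop("intercept bracket failed: hi=", hi) }
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < 1e-12) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  stop("intercept calibration did not converge in ", maxIter,
       " iterations; bracket [", lo, ", ", hi, "]")
}

#' Build a simulation configuration
#'
#' Defaults reproduce the statistical structure of the motivating study:
#' n = 8840 participants, the ten-variant panel of [studyVariants()] with
#' its published minor-allele frequencies and per-allele odds ratios as
#' generating values, covariate effects echoing the published cohort
#' characteristics, and a case prevalence of 9.9%.
#'
#' @param nSamples cohort size.
#' @param variants `data.frame` with `id`, `maf` and `log_or` (per
#'   minor-allele log odds ratio) columns; extra metadata columns
#'   (`chromosome`, `position`, alleles, `risk_allele`) are carried along.
#' @param covariateEffects named log-OR vector; supported names:
#'   `age` (per year, centered at 52), `bmi` (per kg/m^2, centered at
#'   24.6), `sex_male`, `residence_city`, `smoking_current`,
#'   `smoking_former`.
#' @param epistasis optional planted epistasis: `list(snps = <ids>,
#'   offsets = <numeric of length 3^k>)` of log-odds offsets indexed by
#'   the base-3 genotype code of the subset (first SNP varies fastest).
#' @param prsEffect optional category-level disease model:
#'   `list(snps, riskAlleles, lowMax, highMin, logOrMid, logOrHigh)`;
#'   `riskAlleles` is a character vector (`"minor"`/`"major"`) aligned
#'   with `snps`.
#' @param gxe optional gene-lifestyle interaction (requires `prsEffect`):
#'   `list(exposure, pHigh, logOrMidLow, logOrHighLow, logOrMidHigh,
#'   logOrHighHigh)` where `...Low`/`...High` are the PRS-category
#'   log-ORs within the low and high exposure stratum.
#' @param continuousTrait parameters of the FEV1/FVC ratio model:
#'   `list(baseline, slopePerRiskAllele, exposureMultiplier, noiseSd)`.
#' @param outcomeModel `"logistic"` draws case status from the logistic
#'   model and then spirometry consistent with it; `"ratio"` draws the
#'   FEV1/FVC ratio from the continuous trait model (additive in risk
#'   alleles, steeper in the low-exposure stratum) and derives case
#'   status from it via [defineCopdStatus()].
#' @param targetPrevalence target case fraction in (0, 1).
#' @return a `list` of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nSamples = 8840,
                             variants = NULL,
                             covariateEffects = c(
                               age = 0.04, bmi = -0.03,
                               sex_male = log(1.503),
                               residence_city = log(0.786)),
                             epistasis = NULL,
                             prsEffect = NULL,
                             gxe = NULL,
                             continuousTrait = list(
                               baseline = 0.82,
                               slopePerRiskAllele = 0.008,
                               exposureMultiplier = 1.5,
                               noiseSd = 0.06),
                             outcomeModel = c("logistic", "ratio"),
                             targetPrevalence = 0.099) {
  if (is.null(variants)) {
    sv <- studyVariants()
    variants <- data.frame(sv[, c("id", "chromosome", "position",
                                  "minor_allele", "major_allele", "maf")],
                           log_or = log(sv$or_adj),
                           stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants)
  stopifnot(all(c("id", "maf") %in% names(variants)))
  if (is.null(variants$log_or)) variants$log_or <- 0
  if (any(variants$maf <= 0 | variants$maf > 0.5))
    stop("variant MAFs must lie in (0, 0.5]")
  if (!is.null(epistasis)) {
    k <- length(epistasis$snps)
    if (length(epistasis$offsets) != 3^k)
      stop("epistasis offset table must have exactly 3^k = ", 3^k,
           " entries")
    if (!all(epistasis$snps %in% variants$id))
      stop("epistasis SNPs absent from variant list: ",
           paste(setdiff(epistasis$snps, variants$id), collapse = ", "))
  }
  if (!is.null(prsEffect)) {
    if (!all(prsEffect$snps %in% variants$id))
      stop("PRS-model SNPs absent from variant list: ",
           paste(setdiff(prsEffect$snps, variants$id), collapse = ", "))
    prsEffect <- modifyList(list(lowMax = 4, highMin = 7,
                                 logOrMid = NA, logOrHigh = NA),
                            prsEffect)
    if (is.null(prsEffect$riskAlleles))
      stop("prsEffect$riskAlleles ('minor'/'major' per SNP) is required")
  }
  if (!is.null(gxe)) {
    if (is.null(prsEffect))
      stop("gxe requires a prsEffect defining the PRS categories")
    gxe <- modifyList(list(exposure = "w3_en_pct", pHigh = 0.5), gxe)
  }
  stopifnot(targetPrevalence > 0, targetPrevalence < 1)
  structure(list(nSamples = nSamples, variants = variants,
                 covariateEffects = covariateEffects,
                 epistasis = epistasis, prsEffect = prsEffect, gxe = gxe,
                 continuousTrait = continuousTrait,
                 outcomeModel = match.arg(outcomeModel),
                 targetPrevalence = targetPrevalence),
            class = "SimulationConfig")
}

.truncNorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

.simCovariates <- function(n, gxe = NULL) {
  ph <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    age = .truncNorm(n, 52, 8, 40, 69),
    sex = factor(ifelse(runif(n) < 0.47, "male", "female"),
                 levels = c("female", "male")),
    bmi = rnorm(n, 24.6, 3),
    residence = factor(ifelse(runif(n) < 0.53, "city", "rural"),
                       levels = c("rural", "city")),
    chemical_job = runif(n) < 0.071,
    dust_job = runif(n) < 0.181,
    smoking = factor(sample(c("never", "former", "current"), n,
                            replace = TRUE, prob = c(0.60, 0.155, 0.245)),
                     levels = c("never", "former", "current")),
    alcohol_g_day = ifelse(runif(n) < 0.35, 0, rgamma(n, 1.2, rate = 0.1)),
    exercise_min_week = ifelse(runif(n) < 0.5, 0,
                               rgamma(n, 1.8, rate = 1 / 160)),
    asthma_medication = runif(n) < 0.012,
    energy_eer_pct = rnorm(n, 101, 15),
    carb_en_pct = rnorm(n, 70.6, 5),
    protein_en_pct = rnorm(n, 13.6, 2.5),
    fat_en_pct = rnorm(n, 14.4, 4.5),
    w3_en_pct = rgamma(n, shape = 3, rate = 3 / 0.51),
    w6_en_pct = pmax(rnorm(n, 3.36, 1), 0.1),
    fiber_g = rgamma(n, shape = 4, rate = 4 / 15),
    vitC_mg = rgamma(n, shape = 2.5, rate = 2.5 / 90),
    vitD_ug = rgamma(n, shape = 2, rate = 2 / 6),
    total_polyphenol_mg = pmax(rnorm(n, 2062, 600), 0),
    coffee_cups_day = rgamma(n, shape = 1.4, rate = 1.4 / 1.2),
    stringsAsFactors = FALSE)
  if (!is.null(gxe)) {
    # draw the interacting exposure around its cutoff so that the high
    # stratum has the requested prevalence exactly in expectation
    cuts <- lifestyleCutoffs()
    cutoff <- cuts$cutoff[match(gxe$exposure, cuts$exposure)]
    if (is.na(cutoff)) cutoff <- median(ph[[gxe$exposure]], na.rm = TRUE)
    high <- runif(n) < gxe$pHigh
    spread <- max(cutoff * 0.3, 0.1)
    val <- ifelse(high, cutoff + abs(rnorm(n, 0, spread)),
                  pmax(cutoff - abs(rnorm(n, 0, spread)) -
                         spread * 0.01, 0))
    ph[[gxe$exposure]] <- val
  }
  ph
}

.covariateEta <- function(ph, effects) {
  eta <- numeric(nrow(ph))
  for (nm in names(effects)) {
    b <- effects[[nm]]
    eta <- eta + b * switch(nm,
      age = ph$age - 52,
      bmi = ph$bmi - 24.6,
      sex_male = as.numeric(ph$sex == "male"),
      residence_city = as.numeric(ph$residence == "city"),
      smoking_current = as.numeric(ph$smoking == "current"),
      smoking_former = as.numeric(ph$smoking == "former"),
      stop("unsupported covariate effect: ", nm))
  }
  eta
}

.riskDosage <- function(g, riskAlleles) {
  # g: samples x snps dosage of the *minor* allele
  out <- g
  isMajor <- riskAlleles == "major"
  out[, isMajor] <- 2L - g[, isMajor, drop = FALSE]
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates genotypes (independent Hardy-Weinberg columns at the
#' configured MAFs), covariates and lifestyle exposures, then draws case
#' status from a logistic model combining per-allele effects, covariate
#' effects, an optional planted epistasis cell offset and an optional
#' PRS-category / gene-lifestyle term, with the intercept calibrated by
#' [calibrateIntercept()] so the expected prevalence over the realized
#' cohort equals the target. Spirometry (FVC, FEV1/FVC and hence FEV1) is
#' drawn consistently with case status so that [defineCopdStatus()]
#' reproduces it; in `"ratio"` mode the ratio is instead additive in risk
#' alleles (steeper in the low-exposure stratum) and case status derives
#' from the ratio. Fully reproducible from `seed`; the configuration plus
#' the realized intercept are stored as ground truth in the result's
#' metadata.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed (applied locally; global RNG state is
#'   restored on exit).
#' @return [CohortExperiment] with `groundTruth()` set.
#' @examples
#' ce <- simulateCohort(simulationConfig(nSamples = 200), seed = 7)
#' ce
#' @export
simulateCohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(seed, .simulateCohortImpl(config, seed))
}

.simulateCohortImpl <- function(config, seed) {
  n <- config$nSamples
  vars <- config$variants
  m <- nrow(vars)
  g <- matrix(0L, n, m, dimnames = list(NULL, vars$id))
  for (j in seq_len(m)) g[, j] <- simulateGenotypes(vars$maf[j], n)

  ph <- .simCovariates(n, config$gxe)
  rownames(g) <- ph$sample_id
  eta <- as.vector(g %*% vars$log_or) +
    .covariateEta(ph, config$covariateEffects)

  if (!is.null(config$epistasis)) {
    idx <- match(config$epistasis$snps, vars$id)
    code <- .cellCode(g[, idx, drop = FALSE])
    eta <- eta + config$epistasis$offsets[code + 1L]
  }

  prsCat <- NULL
  if (!is.null(config$prsEffect)) {
    pe <- config$prsEffect
    rd <- .riskDosage(g[, pe$snps, drop = FALSE], pe$riskAlleles)
    prs <- rowSums(rd)
    prsCat <- prsCategory(prs, lowMax = pe$lowMax, highMin = pe$highMin)
    if (is.null(config$gxe)) {
      eta <- eta + ifelse(prsCat == "middle", pe$logOrMid,
                          ifelse(prsCat == "high", pe$logOrHigh, 0))
    } else {
      gx <- config$gxe
      expHigh <- dichotomizeLifestyle(ph, gx$exposure) == "high"
      mid <- ifelse(expHigh, gx$logOrMidHigh, gx$logOrMidLow)
      hig <- ifelse(expHigh, gx$logOrHighHigh, gx$logOrHighLow)
      eta <- eta + ifelse(prsCat == "middle", mid,
                          ifelse(prsCat == "high", hig, 0))
    }
  }

  b0 <- calibrateIntercept(eta, config$targetPrevalence)

  ct <- config$continuousTrait
  if (config$outcomeModel == "logistic") {
    y <- runif(n) < plogis(b0 + eta)
    ratio <- numeric(n)
    ratio[y] <- pmax(0.7 - abs(rnorm(sum(y), 0, 0.045)) - 0.005, 0.35)
    ratio[!y] <- pmin(0.7 + abs(rnorm(sum(!y), 0, 0.15)), 0.95)
  } else {
    riskTotal <- if (!is.null(config$prsEffect)) {
      rowSums(.riskDosage(g[, config$prsEffect$snps, drop = FALSE],
                          config$prsEffect$riskAlleles))
    } else rowSums(g)
    slope <- rep(ct$slopePerRiskAllele, n)
    if (!is.null(config$gxe)) {
      expLow <- dichotomizeLifestyle(ph, config$gxe$exposure) == "low"
      slope[expLow] <- slope[expLow] * ct$exposureMultiplier
    }
    ratio <- rnorm(n, ct$baseline - slope * riskTotal, ct$noiseSd)
    ratio <- pmin(pmax(ratio, 0.3), 0.98)
    y <- ratio < 0.7
  }
  ph$fvc <- .truncNorm(n, 3.5, 0.6, 1.5, 6)
  ph$fev1 <- ratio * ph$fvc
  ph$fev1_pct_predicted <- ifelse(y, rnorm(n, 92.5, 12), rnorm(n, 113.8, 12))
  ph$physician_copd_dx <- y & runif(n) < 0.33
  ph$copd <- defineCopdStatus(ph$fev1, ph$fvc, ph$physician_copd_dx,
                              rule = "spirometry_or_dx")

  vmeta <- vars
  for (col in c("chromosome", "position", "minor_allele", "major_allele"))
    if (is.null(vmeta[[col]]))
      vmeta[[col]] <- switch(col, chromosome = NA_character_,
                             position = NA_integer_,
                             minor_allele = "a", major_allele = "b")
  ce <- CohortExperiment(g, vmeta[, c(REQUIRED_VARIANT_COLS,
                                      setdiff(names(vmeta),
                                              REQUIRED_VARIANT_COLS))],
                         ph)
  metadata(ce)$ground_truth <- list(config = config, intercept = b0,
                                    seed = seed)
  ce
}
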