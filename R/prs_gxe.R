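#' Determine the risk allele of each model SNP
#'
#' The risk allele is the allele whose adjusted scan odds ratio exceeds
#' one: the minor allele when `or_adj > 1`, the major allele when
#' `or_adj < 1` (a protective minor allele means the major allele carries
#' the risk).
#'
#' @param scan `data.frame` from [logisticScan()] (or any table with `id`
#'   and `or_adj`).
#' @param modelSnps variant ids of the selected model.
#' @return `data.frame` with columns `id`, `risk_allele`
#'   (`"minor"`/`"major"`) and `or_adj`.
#' @export
riskAlleleMap <- function(scan, modelSnps) {
  hit <- match(modelSnps, scan$id)
  if (anyNA(hit))
    stop("model SNPs missing from scan results: ",
         paste(modelSnps[is.na(hit)], collapse = ", "))
  or_adj <- scan$or_adj[hit]
  data.frame(id = modelSnps,
             risk_allele = ifelse(or_adj > 1, "minor", "major"),
             or_adj = or_adj, stringsAsFactors = FALSE)
}

#' Unweighted risk-allele polygenic risk score
#'
#' The PRS is the plain sum of risk-allele copies across the model SNPs:
#' the minor-allele dosage where the minor allele is the risk allele, and
#' `2 - dosage` where the major allele is. Missing genotypes either
#' exclude the sample (`missingRule = "exclude"`, the default: its PRS
#' and category become `NA`) or are imputed by the expected risk-allele
#' dosage `2 * risk-allele frequency` estimated from the cohort
#' (`"impute_expected"`).
#'
#' @param x a [CohortExperiment] or samples-by-variants dosage matrix.
#' @param riskMap `data.frame` from [riskAlleleMap()].
#' @param cutoffs `c(lowMax, highMin)` passed to [prsCategory()];
#'   defaults to the five-SNP model's published cutoffs (<=4 / 5-6 / >=7).
#' @param missingRule `"exclude"` or `"impute_expected"`.
#' @return `data.frame` with `sample_id`, `prs`, `category`,
#'   `n_missing_snps`.
#' @examples
#' # risk dosages (2, 2, 1, 0, 2) sum to 7 -> "high" in the 5-SNP model
#' @export
computePrs <- function(x, riskMap, cutoffs = c(4, 7),
                       missingRule = c("exclude", "impute_expected")) {
  missingRule <- match.arg(missingRule)
  d <- if (is(x, "CohortExperiment")) dosages(x) else as.matrix(x)
  absent <- setdiff(riskMap$id, colnames(d))
  if (length(absent))
    stop("model SNP(s) absent from cohort: ",
         paste(absent, collapse = ", "))
  g <- d[, riskMap$id, drop = FALSE]
  rd <- .riskDosage(g, riskMap$risk_allele)
  nMiss <- rowSums(is.na(rd))
  if (missingRule == "impute_expected") {
    raf <- colMeans(rd, na.rm = TRUE) / 2  # risk-allele frequency
    for (j in seq_len(ncol(rd))) {
      miss <- is.na(rd[, j])
      rd[miss, j] <- 2 * raf[j]
    }
    prs <- rowSums(rd)
  } else {
    prs <- rowSums(rd)  # NA wherever any SNP is missing
  }
  data.frame(sample_id = rownames(d), prs = prs,
             category = prsCategory(prs, cutoffs[1], cutoffs[2]),
             n_missing_snps = nMiss, stringsAsFactors = FALSE)
}

#' Categorize a PRS into Low / Middle / High
#'
#' `low` when `prs <= lowMax`, `high` when `prs >= highMin`, `middle`
#' otherwise. The published cutoffs are (4, 7) for the five-SNP model,
#' (6, 9) for the seven-SNP model and (7, 10) for the eight-SNP model.
#'
#' @param prs numeric risk-allele counts (fractional allowed under
#'   expected-dosage imputation).
#' @param lowMax,highMin category boundaries; `lowMax < highMin - 1` must
#'   hold so a middle band exists.
#' @return factor with levels `c("low", "middle", "high")`.
#' @examples
#' prsCategory(c(4, 6, 7), 4, 7)
#' @export
prsCategory <- function(prs, lowMax = 4, highMin = 7) {
  if (lowMax >= highMin - 1)
    stop("invalid cutoffs: need lowMax < highMin - 1")
  factor(ifelse(prs <= lowMax, "low",
                ifelse(prs >= highMin, "high", "middle")),
         levels = c("low", "middle", "high"))
}

.waldOrRow <- function(b, se) {
  b <- unname(b); se <- unname(se)
  z <- qnorm(0.975)
  c(or = exp(b), ci_lo = exp(b - z * se), ci_hi = exp(b + z * se),
    p = 2 * pnorm(-abs(b / se)))
}

#' Adjusted odds ratios by PRS category
#'
#' Logistic regression of case status on the PRS category (low as the
#' reference) plus covariates; Wald 95% confidence intervals. Empty
#' categories are dropped with a warning.
#'
#' @param pheno phenotype `data.frame` containing the outcome and
#'   covariates.
#' @param category factor from [computePrs()]/[prsCategory()] aligned
#'   with `pheno` rows.
#' @param covariates covariate column names.
#' @param outcome binary outcome column.
#' @return `data.frame`, one row per category: `category`, `n`,
#'   `n_cases`, `or`, `ci_lo`, `ci_hi`, `p`, `flagged`; the reference row
#'   has `or = 1`.
#' @export
adjustedCategoryOr <- function(pheno, category,
                               covariates = covariateSet("set1"),
                               outcome = "copd") {
  y <- as.numeric(pheno[[outcome]])
  category <- factor(category, levels = levels(factor(category)))
  present <- table(category)
  if (any(present == 0)) {
    warning("empty PRS categor(ies) dropped: ",
            paste(names(present)[present == 0], collapse = ", "))
    category <- droplevels(category)
  }
  lev <- levels(category)
  if (length(lev) < 2)
    stop("need at least two populated PRS categories")
  ok <- !is.na(y) & !is.na(category) & (if (length(covariates))
    complete.cases(pheno[covariates]) else TRUE)
  catMM <- stats::model.matrix(~ category, data =
                                 data.frame(category = category[ok]))
  X <- catMM
  if (length(covariates)) {
    covMM <- stats::model.matrix(
      ~ ., data = pheno[ok, covariates, drop = FALSE])[, -1, drop = FALSE]
    X <- cbind(X, covMM)
  }
  fit <- .logitFit(X, y[ok])
  ncat <- length(lev)
  rows <- lapply(seq_along(lev), function(i) {
    ni <- sum(category[ok] == lev[i])
    ci <- sum(y[ok] == 1 & category[ok] == lev[i])
    if (i == 1)
      return(data.frame(category = lev[i], n = ni, n_cases = ci, or = 1,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        flagged = FALSE, stringsAsFactors = FALSE))
    w <- .waldOrRow(fit$coef[i], fit$se[i])
    data.frame(category = lev[i], n = ni, n_cases = ci,
               or = unname(w["or"]), ci_lo = unname(w["ci_lo"]),
               ci_hi = unname(w["ci_hi"]), p = unname(w["p"]),
               flagged = fit$flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PRS-by-lifestyle interaction test
#'
#' Logistic model with the PRS category as an ordinal trend term
#' (low/middle/high coded 0/1/2), the dichotomized exposure, their
#' product, and covariates; the interaction p-value is the Wald p of the
#' product term (a single-degree-of-freedom trend-by-exposure test).
#'
#' @param pheno phenotype `data.frame`.
#' @param category PRS category factor.
#' @param exposure factor with levels `c("low","high")` from
#'   [dichotomizeLifestyle()].
#' @param covariates covariate columns.
#' @param outcome binary outcome column.
#' @return `list(p_interaction, estimate, se, flagged, model)`; `flagged`
#'   is `TRUE` (with `p_interaction = NA`) when the fit fails or an
#'   exposure stratum has no cases.
#' @export
interactionTest <- function(pheno, category, exposure,
                            covariates = covariateSet("set2"),
                            outcome = "copd") {
  y <- as.numeric(pheno[[outcome]])
  exposure <- factor(exposure, levels = c("low", "high"))
  if (length(unique(na.omit(exposure))) < 2)
    stop("exposure is constant; cannot test an interaction")
  prsOrd <- as.numeric(factor(category,
                              levels = c("low", "middle", "high"))) - 1
  ok <- !is.na(y) & !is.na(prsOrd) & !is.na(exposure) &
    (if (length(covariates)) complete.cases(pheno[covariates]) else TRUE)
  expHigh <- as.numeric(exposure[ok] == "high")
  caseByStratum <- tapply(y[ok], expHigh, sum)
  strataNoCases <- any(caseByStratum == 0)
  X <- cbind(`(Intercept)` = 1, prs = prsOrd[ok], exposure = expHigh,
             `prs:exposure` = prsOrd[ok] * expHigh)
  if (length(covariates)) {
    covMM <- stats::model.matrix(
      ~ ., data = pheno[ok, covariates, drop = FALSE])[, -1, drop = FALSE]
    X <- cbind(X, covMM)
  }
  fit <- .logitFit(X, y[ok])
  flagged <- fit$flagged || strataNoCases
  b <- fit$coef[4]; se <- fit$se[4]
  list(p_interaction = if (flagged) NA_real_
                       else unname(2 * pnorm(-abs(b / se))),
       estimate = unname(b), se = unname(se), flagged = flagged,
       model = paste("logit(outcome) ~ prs_trend * exposure +",
                     if (length(covariates))
                       paste(covariates, collapse = " + ") else "1"))
}

#' Stratified adjusted PRS-category odds ratios
#'
#' Runs [adjustedCategoryOr()] separately within the low and high
#' exposure strata, as done after a significant interaction. Strata with
#' fewer than 30 samples are flagged.
#'
#' @inheritParams interactionTest
#' @param covariates covariate columns used within each stratum.
#' @return named list with elements `low` and `high` (each an
#'   [adjustedCategoryOr()] table with an added `stratum` column and a
#'   `small_stratum` attribute).
#' @export
stratifiedOr <- function(pheno, category, exposure,
                         covariates = covariateSet("set1"),
                         outcome = "copd") {
  exposure <- factor(exposure, levels = c("low", "high"))
  out <- lapply(c(low = "low", high = "high"), function(s) {
    idx <- !is.na(exposure) & exposure == s
    if (!sum(idx)) stop("stratum '", s, "' is empty")
    tab <- adjustedCategoryOr(pheno[idx, , drop = FALSE],
                              category[idx], covariates, outcome)
    tab$stratum <- s
    attr(tab, "small_stratum") <- sum(idx) < 30
    tab
  })
  out
}

#' Covariate-adjusted group means of a continuous outcome
#'
#' Linear model of the outcome on the group factor plus covariates;
#' adjusted means are the model predictions at the covariate means
#' (estimated marginal means) and all pairwise group differences are
#' tested with Tukey adjustment. With no covariates the adjusted means
#' equal the raw group means exactly.
#'
#' @param response numeric outcome (e.g. the FEV1/FVC ratio).
#' @param group factor (e.g. PRS category, or PRS-category-by-exposure).
#' @param pheno phenotype `data.frame` supplying covariates.
#' @param covariates covariate column names.
#' @return `list(means = <data.frame group/mean/se>, contrasts =
#'   <data.frame of Tukey-adjusted pairwise differences>)`.
#' @export
adjustedMeans <- function(response, group, pheno = NULL,
                          covariates = character(0)) {
  dat <- data.frame(.y = response, .group = factor(group))
  if (length(covariates)) {
    stopifnot(!is.null(pheno))
    dat <- cbind(dat, pheno[covariates])
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  form <- as.formula(paste(".y ~ .group",
                           if (length(covariates))
                             paste("+", paste(covariates,
                                              collapse = " + "))
                           else ""))
  fit <- lm(form, data = dat)
  alias <- stats::alias(fit)$Complete
  if (!is.null(alias))
    stop("singular design; collinear column(s): ",
         paste(rownames(alias), collapse = ", "))
  emm <- emmeans::emmeans(fit, ".group")
  means <- as.data.frame(emm)
  names(means)[names(means) == ".group"] <- "group"
  contrasts <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                               adjust = "tukey"))
  list(means = means[, c("group", "emmean", "SE")],
       contrasts = contrasts)
}
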