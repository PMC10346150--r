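#' Hardy-Weinberg exact test
#'
#' Exact conditional test on genotype counts: given the observed allele
#' totals, the p-value is the sum of probabilities of all heterozygote
#' counts whose point probability does not exceed that of the observed
#' table. Probabilities are computed by the standard heterozygote-count
#' recurrence. A monomorphic variant has only one possible configuration
#' and returns p = 1.
#'
#' @param nAA,nAa,naa genotype counts (homozygous, heterozygous,
#'   homozygous other).
#' @return exact p-value.
#' @examples
#' hweExactTest(25, 50, 25)
#' hweExactTest(10, 80, 10)   # heterozygote excess
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(length(nAA) == 1, length(nAa) == 1, length(naa) == 1,
            nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("all genotype counts are zero")
  r <- min(2 * nAA + nAa, 2 * naa + nAa)  # rare-allele count
  if (r == 0) return(1)
  hs <- seq(r %% 2, r, by = 2)
  # unnormalized probabilities via the ratio recurrence
  # P(h+2)/P(h) = 4 * a_h * b_h / ((h+1)(h+2)),
  # a_h = (r-h)/2 rare homozygotes, b_h = n - h - a_h common homozygotes
  p <- numeric(length(hs))
  p[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1)) {
      h <- hs[i]
      a <- (r - h) / 2
      b <- n - h - a
      p[i + 1] <- p[i] * 4 * a * b / ((h + 1) * (h + 2))
      if (!is.finite(p[i + 1])) stop("overflow in HWE recurrence")
      if (p[i + 1] > 1e250) {  # rescale to avoid overflow
        p <- p / p[i + 1]
      }
    }
  }
  p <- p / sum(p)
  obs <- p[hs == nAa]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Variant quality control
#'
#' Drops variants with a missing-call rate at or above `maxMissingRate`
#' (the boundary excludes, mirroring a ">= 4%" exclusion rule), minor
#' allele frequency below `minMaf`, or Hardy-Weinberg exact p strictly
#' below `hweAlpha` (a variant at exactly the alpha is kept). The HWE test
#' uses all samples, cases and controls together. The report accounts for
#' every input variant.
#'
#' @param x a [CohortExperiment].
#' @param maxMissingRate,minMaf,hweAlpha thresholds; defaults 0.04, 0,
#'   0.05.
#' @return `list(cohort = <filtered CohortExperiment>, report =
#'   <data.frame>)`; the report has one row per input variant with its
#'   missing rate, MAF, HWE p, pass flag and drop reason.
#' @export
qcFilter <- function(x, maxMissingRate = 0.04, minMaf = 0,
                     hweAlpha = 0.05) {
  stopifnot(maxMissingRate > 0, maxMissingRate < 1,
            hweAlpha > 0, hweAlpha < 1)
  d <- dosages(x)
  if (ncol(d) == 0) stop("empty genotype matrix")
  stats <- lapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    miss <- mean(is.na(g))
    gg <- g[!is.na(g)]
    maf <- if (length(gg)) mean(gg) / 2 else NA_real_
    counts <- tabulate(gg + 1L, nbins = 3L)
    hwe <- if (length(gg)) hweExactTest(counts[3], counts[2], counts[1])
           else NA_real_
    c(miss = miss, maf = maf, hwe = hwe)
  })
  stats <- do.call(rbind, stats)
  reason <- rep(NA_character_, ncol(d))
  reason[!is.na(stats[, "hwe"]) & stats[, "hwe"] < hweAlpha] <- "hwe"
  reason[stats[, "maf"] < minMaf] <- "maf"
  reason[stats[, "miss"] >= maxMissingRate] <- "missing"
  pass <- is.na(reason)
  report <- data.frame(id = colnames(d),
                       missing_rate = stats[, "miss"],
                       maf = stats[, "maf"], hwe_p = stats[, "hwe"],
                       pass = pass, reason = reason,
                       stringsAsFactors = FALSE)
  if (!any(pass))
    message("qcFilter: no variants survive QC")
  filtered <- CohortExperiment(d[, pass, drop = FALSE],
                               variantInfo(x)[pass, , drop = FALSE],
                               phenotypes(x))
  metadata(filtered)$ground_truth <- metadata(x)$ground_truth
  list(cohort = filtered, report = report)
}

# maximum-likelihood logistic fit returning Wald statistics;
# flags non-convergence and (quasi-)separation
.logitFit <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial(),
                                  control = list(epsilon = 1e-12,
                                                 maxit = 50)))
  p <- ncol(X)
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  flagged <- !fit$converged || is.null(cov) ||
    any(abs(fit$coefficients) > 15, na.rm = TRUE) ||
    any(is.na(fit$coefficients))
  se <- if (is.null(cov)) rep(NA_real_, p) else sqrt(diag(cov))
  # glm.fit pivots columns in its QR; map SEs back to input order
  if (!is.null(cov)) {
    piv <- fit$qr$pivot[seq_len(p)]
    se[piv] <- se
  }
  list(coef = fit$coefficients, se = se, converged = fit$converged,
       flagged = flagged)
}

#' Covariate-adjusted per-variant logistic screen
#'
#' Fits, per variant, a maximum-likelihood logistic regression of case
#' status on the additive minor-allele dosage plus the requested
#' covariates, on the samples with complete data for that variant
#' (complete-case per variant). Reports the per-minor-allele odds ratio,
#' the Wald standard error of the log-OR, the Wald p, the variant's MAF
#' and Hardy-Weinberg exact p, and the sample count used. Non-converged
#' or separated fits are flagged with a missing p-value.
#'
#' @param x a [CohortExperiment] whose phenotypes contain the binary
#'   outcome and the covariates.
#' @param covariates character vector of phenotype columns (see
#'   [covariateSet()]); `character(0)` for an unadjusted screen.
#' @param outcome name of the logical outcome column (default `"copd"`).
#' @return `data.frame` with columns `id`, `or_adj`, `se`, `p`, `maf`,
#'   `hwe_p`, `n_used`, `flagged`.
#' @export
logisticScan <- function(x, covariates = covariateSet("gwas"),
                         outcome = "copd") {
  ph <- phenotypes(x)
  if (!outcome %in% names(ph)) stop("outcome column '", outcome,
                                    "' not found")
  y_all <- as.numeric(ph[[outcome]])
  if (!all(y_all %in% c(0, 1, NA)))
    stop("outcome must be binary")
  missingCov <- setdiff(covariates, names(ph))
  if (length(missingCov))
    stop("covariate column(s) not found: ",
         paste(missingCov, collapse = ", "))
  covMM <- if (length(covariates)) {
    mf <- ph[covariates]
    stats::model.matrix(~ ., data = mf)[, -1, drop = FALSE]
  } else NULL
  covComplete <- if (length(covariates))
    complete.cases(ph[covariates]) else rep(TRUE, nrow(ph))

  d <- dosages(x)
  res <- lapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    gg <- g[!is.na(g)]
    counts <- tabulate(gg + 1L, nbins = 3L)
    maf <- mean(gg) / 2
    hwe <- hweExactTest(counts[3], counts[2], counts[1])
    ok <- !is.na(g) & !is.na(y_all) & covComplete
    X <- cbind(`(Intercept)` = 1, dosage = g[ok])
    if (!is.null(covMM)) {
      # covariate rows must align with the retained samples
      idx <- which(covComplete)
      X <- cbind(X, covMM[match(which(ok), idx), , drop = FALSE])
    }
    fit <- tryCatch(.logitFit(X, y_all[ok]), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(id = colnames(d)[j], or_adj = NA_real_,
                        se = NA_real_, p = NA_real_, maf = maf,
                        hwe_p = hwe, n_used = sum(ok), flagged = TRUE))
    b <- fit$coef[2]; se <- fit$se[2]
    p <- if (fit$flagged) NA_real_ else 2 * pnorm(-abs(b / se))
    data.frame(id = colnames(d)[j], or_adj = exp(b), se = se, p = p,
               maf = maf, hwe_p = hwe, n_used = sum(ok),
               flagged = fit$flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select screen candidates by p-value threshold
#'
#' Variants with p strictly below the threshold, sorted by ascending p.
#' A variant at exactly the threshold is excluded.
#'
#' @param results `data.frame` from [logisticScan()].
#' @param pThreshold significance threshold (default 5e-5).
#' @return character vector of variant ids.
#' @export
selectCandidates <- function(results, pThreshold = 5e-5) {
  keep <- !is.na(results$p) & results$p < pThreshold
  results$id[keep][order(results$p[keep])]
}

#' Genomic inflation factor and Q-Q data
#'
#' lambda is the median of the one-degree chi-square quantiles of the
#' observed p-values divided by the null median 0.4549 (the median-based
#' genomic-control estimator). Fewer than 100 p-values give an unstable
#' median; the estimate is then flagged.
#'
#' @param results a [logisticScan()] `data.frame`, or a numeric vector of
#'   p-values.
#' @return `list(lambda_gc, n, low_confidence, qq)` where `qq` is a
#'   `data.frame` of expected and observed -log10 p sorted by expected
#'   quantile (plus chromosome/position when available for Manhattan
#'   plots).
#' @export
genomicLambda <- function(results) {
  if (is.data.frame(results)) {
    p <- results$p
    meta <- results[c("id")]
  } else {
    p <- results
    meta <- NULL
  }
  p <- p[!is.na(p)]
  if (!length(p)) stop("no non-missing p-values")
  lowConf <- length(p) < 100
  if (lowConf)
    warning("fewer than 100 p-values; lambda estimate is unstable")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chisq) / qchisq(0.5, df = 1, lower.tail = FALSE)
  ord <- order(p)
  qq <- data.frame(expected = -log10(ppoints(length(p))),
                   observed = -log10(p[ord]))
  list(lambda_gc = lambda, n = length(p), low_confidence = lowConf,
       qq = qq)
}

#' Optional per-sample excess-heterozygosity filter
#'
#' Array-QC style screen upstream of the variant analyses: flags samples
#' whose heterozygous-call fraction across variants exceeds the
#' threshold (default 30%), a signature of sample contamination. Not
#' applied by default anywhere in the pipeline; callers subset the
#' cohort with the returned mask if desired.
#'
#' @param x a [CohortExperiment].
#' @param maxHet maximum tolerated heterozygosity fraction.
#' @return logical vector, `TRUE` for samples passing the filter.
#' @export
heterozygosityFilter <- function(x, maxHet = 0.3) {
  d <- dosages(x)
  het <- rowMeans(d == 1L, na.rm = TRUE)
  is.na(het) | het <= maxHet
}
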