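# base-3 cell code for a k-SNP genotype combination; first SNP varies
# fastest; returns codes in 0..3^k-1 (NA if any genotype missing)
.cellCode <- function(g) {
  g <- as.matrix(g)
  code <- rep(0, nrow(g))
  mult <- 1
  for (j in seq_len(ncol(g))) {
    code <- code + g[, j] * mult
    mult <- mult * 3
  }
  code
}

#' GMDR score statistics
#'
#' The per-sample score is the residual y - p-hat from the covariate-only
#' (null) logistic model; it carries the covariate-adjusted outcome
#' information into the cell classification, which is what distinguishes
#' GMDR from unadjusted MDR. At the maximum-likelihood fit with an
#' intercept the scores sum to zero.
#'
#' @param pheno phenotype `data.frame`.
#' @param covariates covariate column names ([covariateSet()]);
#'   `character(0)` gives intercept-only scores y - prevalence.
#' @param outcome binary outcome column name.
#' @return numeric score vector aligned with `pheno` rows (NA where the
#'   outcome or a covariate is missing).
#' @export
scoreStatistics <- function(pheno, covariates = covariateSet("gwas"),
                            outcome = "copd") {
  y <- as.numeric(pheno[[outcome]])
  ok <- !is.na(y) & (if (length(covariates))
    complete.cases(pheno[covariates]) else TRUE)
  X <- if (length(covariates)) {
    stats::model.matrix(~ ., data = pheno[ok, covariates, drop = FALSE])
  } else matrix(1, sum(ok), 1)
  fit <- .logitFit(X, y[ok])
  if (fit$flagged)
    stop("null (covariate-only) logistic model did not converge; ",
         "possible separation")
  phat <- plogis(drop(X %*% fit$coef))
  s <- rep(NA_real_, nrow(pheno))
  s[ok] <- y[ok] - phat
  s
}

#' Multilocus cell table for a SNP subset
#'
#' Maps every training sample to one of the 3^k genotype cells of the
#' subset and labels each cell high-risk when its score sum is positive,
#' low-risk when negative or zero (ties are conservatively low), and
#' `"empty"` when no training sample falls in it. Samples with a missing
#' genotype at any subset SNP are excluded and counted.
#'
#' @param scores score vector from [scoreStatistics()].
#' @param dosage samples-by-variants dosage matrix (see [dosages()]).
#' @param snpSubset character vector of 1-5 variant ids.
#' @param trainIdx indices (or logical mask) of training samples.
#' @return `list(label, score_sum, count, snps, n_excluded)` with one
#'   entry per cell (cells in base-3 order, first SNP fastest).
#' @export
buildCells <- function(scores, dosage, snpSubset, trainIdx) {
  k <- length(snpSubset)
  stopifnot(k >= 1, k <= 5)
  g <- dosage[trainIdx, snpSubset, drop = FALSE]
  s <- scores[trainIdx]
  keep <- complete.cases(g) & !is.na(s)
  n_excluded <- sum(!keep)
  g <- g[keep, , drop = FALSE]; s <- s[keep]
  if (!nrow(g)) stop("no usable training samples")
  code <- .cellCode(g)
  ncell <- 3^k
  score_sum <- numeric(ncell)
  count <- integer(ncell)
  agg <- rowsum(s, code)
  score_sum[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  tab <- table(factor(code, levels = 0:(ncell - 1)))
  count <- as.integer(tab)
  label <- ifelse(count == 0, "empty",
                  ifelse(score_sum > 0, "high", "low"))
  list(label = label, score_sum = score_sum, count = count,
       snps = snpSubset, n_excluded = n_excluded)
}

#' Balanced accuracy of a cell classification
#'
#' Predicts case status for the evaluation samples from their cell label
#' (high = predicted case); samples falling in empty or unseen cells are
#' predicted low-risk. Balanced accuracy is (sensitivity +
#' specificity) / 2.
#'
#' @param cells a cell table from [buildCells()].
#' @param dosage samples-by-variants dosage matrix.
#' @param outcome logical/0-1 case status vector aligned with `dosage`.
#' @param evalIdx indices (or logical mask) of evaluation samples.
#' @return balanced accuracy in `[0, 1]`.
#' @examples
#' # (TP 30, FN 10, TN 50, FP 10) -> (0.75 + 0.8333) / 2 = 0.7917
#' @export
balancedAccuracy <- function(cells, dosage, outcome, evalIdx) {
  g <- dosage[evalIdx, cells$snps, drop = FALSE]
  y <- as.logical(outcome[evalIdx])
  keep <- complete.cases(g) & !is.na(y)
  g <- g[keep, , drop = FALSE]; y <- y[keep]
  if (!any(y) || all(y))
    stop("evaluation set needs both cases and controls")
  code <- .cellCode(g)
  pred <- cells$label[code + 1L] == "high"
  pred[is.na(pred)] <- FALSE
  sens <- mean(pred[y])
  spec <- mean(!pred[!y])
  (sens + spec) / 2
}

#' Exact sign test on cross-validation folds
#'
#' One-sided exact binomial test that the number of folds with test
#' balanced accuracy above 0.5 exceeds chance:
#' P(X >= n_success | n_folds, 1/2).
#'
#' @param nSuccess number of folds with TEBA strictly above 0.5.
#' @param nFolds number of folds (default 10).
#' @return p-value.
#' @examples
#' signTest(10)  # 1/1024
#' signTest(9)   # 11/1024
#' @export
signTest <- function(nSuccess, nFolds = 10) {
  stopifnot(nSuccess >= 0, nSuccess <= nFolds)
  pbinom(nSuccess - 1, nFolds, 0.5, lower.tail = FALSE)
}

# stratified fold assignment: cases and controls are split separately so
# every fold has the cohort's case fraction
.stratifiedFolds <- function(y, nFolds, seed) {
  withr::with_seed(seed, {
    folds <- integer(length(y))
    for (cls in unique(y[!is.na(y)])) {
      idx <- which(!is.na(y) & y == cls)
      folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    folds[is.na(y)] <- NA_integer_
    folds
  })
}

#' Exhaustive GMDR model search with cross-validation
#'
#' For each interaction order k, every k-subset of the candidate SNPs is
#' evaluated in a 10-fold cross-validation stratified by case status: on
#' each fold's 9 training parts the subset's cells are labeled by the
#' sign of their score sums and the subset maximizing trained balanced
#' accuracy (TRBA) is chosen (ties broken lexicographically); its test
#' balanced accuracy (TEBA) is measured on the held-out part.
#' Cross-validation consistency (CVC) is the number of folds choosing the
#' modal subset, and the sign test counts folds with TEBA > 0.5. The
#' reported model per k is the modal subset with fold-averaged TRBA and
#' TEBA.
#'
#' Samples with a missing genotype at any candidate SNP, a missing
#' outcome, or a missing score are excluded up front.
#'
#' @param x a [CohortExperiment], or a samples-by-variants dosage matrix
#'   (then `pheno` is required).
#' @param covariates covariate columns for the score null model; set
#'   `adjusted = FALSE` for raw (unadjusted, MDR-style) scores
#'   y - mean(y).
#' @param candidates candidate variant ids.
#' @param kRange interaction orders to search (subset sizes).
#' @param nFolds number of CV folds.
#' @param seed seed for the stratified fold assignment.
#' @param pheno phenotype `data.frame` when `x` is a matrix.
#' @param outcome binary outcome column.
#' @param folds optional precomputed fold assignment (overrides `seed`).
#' @param adjusted use covariate-adjusted scores (default) or raw scores.
#' @param maxSubsets guard on the number of subsets per k.
#' @return a [GMDRResult-class] object.
#' @export
gmdrSearch <- function(x, covariates = covariateSet("gwas"), candidates,
                       kRange = 1:5, nFolds = 10, seed = 1,
                       pheno = NULL, outcome = "copd", folds = NULL,
                       adjusted = TRUE, maxSubsets = 20000) {
  if (is(x, "CohortExperiment")) {
    dosage <- dosages(x)
    pheno <- phenotypes(x)
  } else dosage <- as.matrix(x)
  stopifnot(!is.null(pheno))
  if (length(candidates) < max(kRange))
    stop("need at least max(kRange) = ", max(kRange), " candidates")
  missing_ids <- setdiff(candidates, colnames(dosage))
  if (length(missing_ids))
    stop("candidates absent from dosage matrix: ",
         paste(missing_ids, collapse = ", "))
  y <- as.logical(pheno[[outcome]])
  scores <- if (adjusted) scoreStatistics(pheno, covariates, outcome)
            else as.numeric(y) - mean(y, na.rm = TRUE)

  usable <- complete.cases(dosage[, candidates, drop = FALSE]) &
    !is.na(y) & !is.na(scores)
  dosage <- dosage[usable, candidates, drop = FALSE]
  y <- y[usable]; scores <- scores[usable]
  if (is.null(folds)) folds <- .stratifiedFolds(y, nFolds, seed)
  else folds <- folds[usable]

  nCase <- tabulate(folds[y], nFolds)
  nCtrl <- tabulate(folds[!y], nFolds)
  if (any(nCase == 0) || any(nCtrl == 0))
    stop("every fold needs both cases and controls; reduce nFolds")

  perFold <- list()
  models <- list()
  for (k in kRange) {
    nSub <- choose(length(candidates), k)
    if (nSub > maxSubsets)
      stop("C(", length(candidates), ",", k, ") = ", nSub,
           " subsets exceeds maxSubsets = ", maxSubsets,
           "; prune candidates or lower k")
    subsets <- combn(candidates, k, simplify = FALSE)
    codes <- lapply(subsets, function(s)
      .cellCode(dosage[, s, drop = FALSE]))
    chosen <- integer(nFolds); trba <- teba <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      train <- folds != f
      bestBA <- -Inf; best <- NA_integer_
      sTr <- scores[train]; yTr <- y[train]
      nCaseTr <- sum(yTr); nCtrlTr <- sum(!yTr)
      for (si in seq_along(subsets)) {
        code <- codes[[si]][train]
        ncell <- 3^k
        ssum <- numeric(ncell)
        agg <- rowsum(sTr, code)
        ssum[as.integer(rownames(agg)) + 1L] <- agg[, 1]
        high <- ssum > 0
        caseTab <- tabulate(code[yTr] + 1L, ncell)
        ctrlTab <- tabulate(code[!yTr] + 1L, ncell)
        ba <- (sum(caseTab[high]) / nCaseTr +
                 sum(ctrlTab[!high]) / nCtrlTr) / 2
        if (ba > bestBA + 1e-12) { bestBA <- ba; best <- si }
      }
      chosen[f] <- best
      trba[f] <- bestBA
      # held-out evaluation with the training-cell labels
      codeTr <- codes[[best]][train]
      ncell <- 3^k
      ssum <- numeric(ncell)
      agg <- rowsum(scores[train], codeTr)
      ssum[as.integer(rownames(agg)) + 1L] <- agg[, 1]
      seen <- tabulate(codeTr + 1L, ncell) > 0
      high <- ssum > 0 & seen          # empty/unseen cells predict low
      codeTe <- codes[[best]][!train]
      yTe <- y[!train]
      pred <- high[codeTe + 1L]
      teba[f] <- (mean(pred[yTe]) + mean(!pred[!yTe])) / 2
    }
    keys <- vapply(chosen, function(i) paste(subsets[[i]],
                                             collapse = ","),
                   character(1))
    tab <- table(keys)
    modal <- names(tab)[tab == max(tab)]
    modal <- sort(modal)[1]
    cvc <- as.integer(max(tab))
    nSuccess <- sum(teba > 0.5)
    models[[as.character(k)]] <- data.frame(
      k = k, snps = modal, trba = mean(trba), teba = mean(teba),
      cvc = cvc, sign_test_p = signTest(nSuccess, nFolds),
      n_folds = nFolds, stringsAsFactors = FALSE)
    perFold[[as.character(k)]] <- data.frame(
      k = k, fold = seq_len(nFolds), snps = keys, trba = trba,
      teba = teba, stringsAsFactors = FALSE)
  }
  new("GMDRResult", models = do.call(rbind, c(models,
                                              make.row.names = FALSE)),
      perFold = do.call(rbind, c(perFold, make.row.names = FALSE)),
      seed = as.integer(seed))
}

#' Select the best GMDR model
#'
#' Among the per-k models passing both the sign-test and the
#' cross-validation-consistency criterion, returns the one with the
#' highest mean TEBA; exact TEBA ties go to the smaller k (the more
#' parsimonious model). The defaults are the stricter reporting
#' thresholds (sign p < 0.001, CVC = 10/10); the screening thresholds
#' p < 0.05 and CVC >= 9 can be requested instead.
#'
#' @param result a [GMDRResult-class] from [gmdrSearch()].
#' @param signAlpha sign-test threshold (strict `<`).
#' @param minCvc minimum cross-validation consistency.
#' @return one-row `data.frame` (the selected model), or a zero-row
#'   `data.frame` with a `"reasons"` attribute naming why each model
#'   failed.
#' @export
selectBestModel <- function(result, signAlpha = 0.001, minCvc = 10) {
  m <- gmdrModels(result)
  pass <- m$sign_test_p < signAlpha & m$cvc >= minCvc
  if (!any(pass)) {
    reasons <- sprintf(
      "k=%d: sign_p=%.4g (%s), cvc=%d (%s)", m$k, m$sign_test_p,
      ifelse(m$sign_test_p < signAlpha, "pass", "fail"), m$cvc,
      ifelse(m$cvc >= minCvc, "pass", "fail"))
    out <- m[0, ]
    attr(out, "reasons") <- reasons
    return(out)
  }
  mm <- m[pass, , drop = FALSE]
  mm <- mm[order(-mm$teba, mm$k), , drop = FALSE]
  mm[1, , drop = FALSE]
}
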