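#' @import methods
#' @importFrom stats as.formula binomial coef complete.cases dbinom glm
#'   glm.fit lm median na.omit pbinom plogis pnorm ppoints qchisq qlogis
#'   qnorm quantile rbinom rgamma rnorm runif sd setNames vcov
#' @importFrom utils combn modifyList read.delim write.table packageVersion
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

REQUIRED_VARIANT_COLS <- c("id", "chromosome", "position",
                           "minor_allele", "major_allele")

#' CohortExperiment: genotype dosages plus phenotypes for one cohort
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' a single `"dosage"` assay (variants in rows, samples in columns; values
#' 0/1/2 count copies of the minor allele, `NA` = missing call), per-variant
#' metadata in `rowData()` (`id`, `chromosome`, `position`, `minor_allele`,
#' `major_allele`) and the per-sample phenotype/covariate table in
#' `colData()`. Cohorts simulated by [simulateCohort()] additionally carry
#' their generating configuration in `metadata()$ground_truth`.
#'
#' @param dosage integer matrix of minor-allele dosages, samples in rows and
#'   variants in columns (the orientation of the on-disk dosage table);
#'   values must be 0, 1, 2 or `NA`.
#' @param variants `data.frame` with one row per variant and at least the
#'   columns `id`, `chromosome`, `position`, `minor_allele`, `major_allele`.
#'   Unknown chromosome/position/alleles may be `NA`.
#' @param phenotypes optional `data.frame` of per-sample variables; if it
#'   has a `sample_id` column it must agree with `rownames(dosage)`.
#'
#' @return A `CohortExperiment` object.
#' @examples
#' gm <- matrix(c(0L, 1L, 2L, 0L), nrow = 2,
#'              dimnames = list(c("s1", "s2"), c("v1", "v2")))
#' vi <- data.frame(id = c("v1", "v2"), chromosome = c("1", "2"),
#'                  position = c(100L, 200L),
#'                  minor_allele = c("A", "C"), major_allele = c("G", "T"))
#' ce <- CohortExperiment(gm, vi)
#' dosages(ce)
#' @export
CohortExperiment <- function(dosage, variants, phenotypes = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- as.data.frame(variants)
  missing_cols <- setdiff(REQUIRED_VARIANT_COLS, names(variants))
  if (length(missing_cols))
    stop("variants table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(variants) != ncol(dosage))
    stop("number of variant rows (", nrow(variants),
         ") does not match dosage columns (", ncol(dosage), ")")
  if (is.null(rownames(dosage))) {
    if (!is.null(phenotypes) && !is.null(phenotypes$sample_id))
      rownames(dosage) <- phenotypes$sample_id
    else rownames(dosage) <- paste0("sample", seq_len(nrow(dosage)))
  }
  colnames(dosage) <- variants$id
  if (is.null(phenotypes))
    phenotypes <- data.frame(sample_id = rownames(dosage))
  phenotypes <- as.data.frame(phenotypes)
  if (is.null(phenotypes$sample_id))
    phenotypes$sample_id <- rownames(dosage)
  if (!identical(as.character(phenotypes$sample_id), rownames(dosage)))
    stop("phenotype sample_id does not match dosage row names")
  se <- SummarizedExperiment(
    assays = list(dosage = t(dosage)),
    rowData = DataFrame(variants, row.names = variants$id),
    colData = DataFrame(phenotypes, row.names = rownames(dosage)))
  new("CohortExperiment", se)
}

#' @rdname CohortExperiment
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
  msgs <- character(0)
  if (!"dosage" %in% assayNames(object))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% 0:2))
    msgs <- c(msgs, "dosage values must be 0, 1, 2 or NA")
  rd <- rowData(object)
  miss <- setdiff(REQUIRED_VARIANT_COLS, colnames(rd))
  if (length(miss))
    msgs <- c(msgs, paste("rowData lacks column(s):",
                          paste(miss, collapse = ", ")))
  else {
    same <- !is.na(rd$minor_allele) & !is.na(rd$major_allele) &
      rd$minor_allele == rd$major_allele
    if (any(same))
      msgs <- c(msgs, "minor and major allele must differ")
    bad_pos <- !is.na(rd$position) & rd$position < 1
    if (any(bad_pos))
      msgs <- c(msgs, "positions must be >= 1 (1-based coordinates)")
    if (anyDuplicated(rd$id))
      msgs <- c(msgs, "variant ids must be unique")
  }
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Accessors for CohortExperiment
#'
#' `dosages()` returns the minor-allele dosage matrix in analysis
#' orientation (samples in rows, variants in columns); `variantInfo()` the
#' per-variant metadata; `phenotypes()` the per-sample table; `sampleIds()`
#' the sample identifiers; `groundTruth()` the generating configuration of
#' a simulated cohort (or `NULL`).
#'
#' @param x a `CohortExperiment`.
#' @return See the individual descriptions.
#' @name cohort-accessors
#' @aliases dosages variantInfo phenotypes sampleIds groundTruth
#' @examples
#' ce <- simulateCohort(simulationConfig(nSamples = 50), seed = 1)
#' dim(dosages(ce))
#' head(variantInfo(ce))
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname cohort-accessors
#' @export
setMethod("dosages", "CohortExperiment", function(x) t(assay(x, "dosage")))

#' @rdname cohort-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname cohort-accessors
#' @export
setMethod("variantInfo", "CohortExperiment", function(x) {
  df <- as.data.frame(rowData(x))
  rownames(df) <- NULL
  df
})

#' @rdname cohort-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname cohort-accessors
#' @export
setMethod("phenotypes", "CohortExperiment", function(x) {
  df <- as.data.frame(colData(x))
  rownames(df) <- NULL
  df
})

#' @rdname cohort-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname cohort-accessors
#' @export
setMethod("sampleIds", "CohortExperiment", function(x) colnames(x))

#' @rdname cohort-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname cohort-accessors
#' @export
setMethod("groundTruth", "CohortExperiment",
          function(x) metadata(x)$ground_truth)

setMethod("show", "CohortExperiment", function(object) {
  cat("CohortExperiment:", ncol(object), "samples x", nrow(object),
      "variants\n")
  ph <- colData(object)
  if ("copd" %in% colnames(ph)) {
    y <- ph$copd
    cat(sprintf("  COPD cases: %d (%.1f%%)\n", sum(y, na.rm = TRUE),
                100 * mean(y, na.rm = TRUE)))
  }
  if (!is.null(metadata(object)$ground_truth))
    cat("  simulated cohort with ground truth (see groundTruth())\n")
  invisible(object)
})

#' Result of a GMDR model search
#'
#' Container returned by [gmdrSearch()]: one summary row per interaction
#' order k (selected SNP subset, mean trained and test balanced accuracy,
#' cross-validation consistency, sign-test p) plus the full per-fold
#' records.
#'
#' @slot models `data.frame` with columns `k`, `snps` (comma-separated
#'   modal subset), `trba`, `teba`, `cvc`, `sign_test_p`, `n_folds`.
#' @slot perFold `data.frame` with one row per (k, fold): chosen subset and
#'   its fold-level TRBA/TEBA.
#' @slot seed integer seed used for fold assignment.
#' @export
setClass("GMDRResult",
         representation(models = "data.frame",
                        perFold = "data.frame",
                        seed = "integer"))

#' @rdname GMDRResult-class
#' @param x a `GMDRResult`.
#' @return `gmdrModels()` returns the per-k summary `data.frame`;
#'   `gmdrFolds()` the per-fold records.
#' @export
setGeneric("gmdrModels", function(x) standardGeneric("gmdrModels"))

#' @rdname GMDRResult-class
#' @export
setMethod("gmdrModels", "GMDRResult", function(x) x@models)

#' @rdname GMDRResult-class
#' @export
setGeneric("gmdrFolds", function(x) standardGeneric("gmdrFolds"))

#' @rdname GMDRResult-class
#' @export
setMethod("gmdrFolds", "GMDRResult", function(x) x@perFold)

setMethod("show", "GMDRResult", function(object) {
  cat("GMDRResult over k =", paste(object@models$k, collapse = ", "), "\n")
  print(object@models, row.names = FALSE)
  invisible(object)
})
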