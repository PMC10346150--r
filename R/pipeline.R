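#' Default pipeline configuration
#'
#' All thresholds default to the published analysis values: QC
#' missing-call rate 4% and HWE alpha 0.05, candidate threshold
#' p = 5e-5, |D'| pruning threshold 0.2, GMDR reporting thresholds
#' (sign p < 0.001, CVC = 10/10), five-SNP PRS cutoffs (<=4 / 5-6 / >=7),
#' and the reference lifestyle cutoffs of [lifestyleCutoffs()].
#'
#' @param ... overrides of the default fields.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    simulate = TRUE,
    simulation = simulationConfig(),
    genotypes = NULL,            # path to VCF/TSV when simulate = FALSE
    phenotypes = NULL,           # path to phenotype TSV
    qc = list(maxMissingRate = 0.04, minMaf = 0, hweAlpha = 0.05),
    pCandidate = 5e-5,
    dPrimeThreshold = 0.2,
    scanCovariates = "gwas",
    kRange = 1:5,
    nFolds = 10,
    signAlpha = 0.001,
    minCvc = 10,
    prsCutoffs = c(4, 7),
    missingRule = "exclude",
    exposures = c("w3_en_pct", "exercise_min_week"),
    orCovariates = c("set1", "set2"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown pipeline config field(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots   # shallow replacement, no deep merging
  cfg
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC + single-SNP screen -> candidate
#' selection -> D' pruning -> GMDR search -> PRS construction and
#' category odds ratios -> lifestyle interaction and stratified analyses,
#' writing every stage's table plus a `manifest.json` (package version,
#' seed, per-stage seeds, file MD5 hashes) into `outDir`. A rerun with
#' the same config and seed reproduces every file bit for bit. A stage
#' failure halts the run with the stage name; tables already written are
#' retained.
#'
#' @param config list from [pipelineConfig()] (or a YAML file path).
#' @param outDir output directory.
#' @param seed master seed; per-stage seeds are derived from it by a
#'   fixed rule so stages are individually reproducible.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, seed = 1) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    config <- modifyList(pipelineConfig(), raw)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stageSeeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, 7))
  files <- character(0)
  stage <- "simulate"
  res <- tryCatch({
    if (isTRUE(config$simulate)) {
      ce <- simulateCohort(config$simulation, seed = stageSeeds[1])
      files <- c(files, writeCohort(ce, file.path(outDir, "cohort")))
    } else {
      ce <- readGenotypes(config$genotypes)
      ph <- readPhenotypes(config$phenotypes)
      ce <- CohortExperiment(dosages(ce), variantInfo(ce), ph)
    }

    stage <- "scan"
    qc <- qcFilter(ce, config$qc$maxMissingRate, config$qc$minMaf,
                   config$qc$hweAlpha)
    files <- c(files, .writeTsv(qc$report,
                                file.path(outDir, "qc_report.tsv")))
    covs <- if (config$scanCovariates %in%
                  c("set1", "set2", "gwas", "none"))
      covariateSet(config$scanCovariates) else config$scanCovariates
    scan <- logisticScan(qc$cohort, covs)
    files <- c(files, .writeTsv(scan, file.path(outDir, "assoc.tsv")))
    gl <- genomicLambda(scan)
    vi <- variantInfo(qc$cohort)
    manh <- data.frame(id = scan$id,
                       chromosome = vi$chromosome[match(scan$id, vi$id)],
                       position = vi$position[match(scan$id, vi$id)],
                       p = scan$p)
    files <- c(files,
               .writeTsv(gl$qq, file.path(outDir, "qq.tsv")),
               .writeTsv(manh, file.path(outDir, "manhattan.tsv")))

    stage <- "prune"
    cand <- selectCandidates(scan, config$pCandidate)
    pvec <- setNames(scan$p, scan$id)
    pruned <- ldPrune(cand, qc$cohort, pvec, config$dPrimeThreshold)
    files <- c(files,
               .writeTsv(pruned$pairs, file.path(outDir, "ld_pairs.tsv")),
               .writeTsv(data.frame(id = pruned$retained),
                         file.path(outDir, "pruned_candidates.tsv")))
    if (length(pruned$retained) < max(config$kRange))
      stop("only ", length(pruned$retained),
           " candidates survive pruning; lower kRange")

    stage <- "gmdr"
    gm <- gmdrSearch(qc$cohort, covs, pruned$retained,
                     kRange = config$kRange, nFolds = config$nFolds,
                     seed = stageSeeds[4])
    files <- c(files,
               .writeTsv(gmdrModels(gm),
                         file.path(outDir, "gmdr_models.tsv")),
               .writeTsv(gmdrFolds(gm),
                         file.path(outDir, "gmdr_folds.tsv")))
    best <- selectBestModel(gm, config$signAlpha, config$minCvc)
    if (!nrow(best))
      stop("no GMDR model passed the selection criteria:\n",
           paste(attr(best, "reasons"), collapse = "\n"))
    modelSnps <- strsplit(best$snps, ",")[[1]]

    stage <- "prs"
    rmap <- riskAlleleMap(scan, modelSnps)
    profiles <- computePrs(qc$cohort, rmap, config$prsCutoffs,
                           config$missingRule)
    files <- c(files, .writeTsv(profiles,
                                file.path(outDir, "prs_profiles.tsv")))
    ph <- phenotypes(qc$cohort)
    orTabs <- lapply(config$orCovariates, function(cs) {
      tab <- adjustedCategoryOr(ph, profiles$category, covariateSet(cs))
      tab$covariate_set <- cs
      tab
    })
    files <- c(files, .writeTsv(do.call(rbind, orTabs),
                                file.path(outDir, "prs_or.tsv")))

    stage <- "interact"
    interRows <- list(); stratRows <- list()
    for (expo in config$exposures) {
      ex <- dichotomizeLifestyle(ph, expo)
      it <- interactionTest(ph, profiles$category, ex,
                            covariateSet("set2"))
      interRows[[expo]] <- data.frame(
        exposure = expo, p_interaction = it$p_interaction,
        estimate = it$estimate, flagged = it$flagged,
        stringsAsFactors = FALSE)
      st <- stratifiedOr(ph, profiles$category, ex, covariateSet("set1"))
      stratRows[[expo]] <- cbind(exposure = expo,
                                 rbind(st$low, st$high))
    }
    files <- c(files,
               .writeTsv(do.call(rbind, c(interRows,
                                          make.row.names = FALSE)),
                         file.path(outDir, "interaction.tsv")),
               .writeTsv(do.call(rbind, c(stratRows,
                                          make.row.names = FALSE)),
                         file.path(outDir, "stratified_or.tsv")))
    # adjusted means of the spirometric ratio by PRS category x exposure
    ratio <- ph$fev1 / ph$fvc
    ex1 <- dichotomizeLifestyle(ph, config$exposures[1])
    grp <- interaction(profiles$category, ex1, sep = ":")
    am <- adjustedMeans(ratio, grp, ph, covariateSet("set1"))
    files <- c(files, .writeTsv(am$means,
                                file.path(outDir, "adjusted_means.tsv")))
    TRUE
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package = "epiPRS",
    version = as.character(packageVersion("epiPRS")),
    seed = seed,
    stage_seeds = as.list(setNames(stageSeeds,
      c("simulate", "qc", "scan", "gmdr", "prs", "interact", "spare"))),
    files = {
      f <- sort(unname(files))
      md5 <- tools::md5sum(f)
      names(md5) <- sub(paste0("^", normalizePath(outDir), "/"), "",
                        normalizePath(f))
      as.list(md5)
    })
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
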