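#' Read genotypes from VCF or dosage TSV
#'
#' Reads biallelic diploid genotypes and recodes them as minor-allele
#' dosages. The minor allele is determined from the sample allele
#' frequencies; at an exact 50/50 tie the alphabetically first allele is
#' taken as minor (a deterministic convention, recorded in the variant
#' metadata). Missing calls (`./.` or `.`) become `NA`. Multi-allelic VCF
#' records and duplicated sample ids are rejected.
#'
#' The dosage-TSV format has a header `sample_id<TAB>var1<TAB>...` and one
#' row per sample with cells 0/1/2/NA, already coded as minor-allele
#' counts. Variant metadata can be supplied through `variants`; otherwise
#' chromosome, position and alleles are recorded as `NA` (unknown).
#'
#' @param path path to a VCF (4.x, `GT` field) or a dosage TSV.
#' @param format `"auto"` (by file extension), `"vcf"` or `"tsv"`.
#' @param variants optional variant metadata `data.frame` for TSV input.
#' @return A [CohortExperiment] (phenotypes empty).
#' @seealso [readPhenotypes()], [writeCohort()]
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          variants = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") .readGenotypesVcf(path) else
    .readGenotypesTsv(path, variants)
}

.readGenotypesVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single record: coerce back to a matrix
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    ids <- ifelse(is.na(fix[multi, "ID"]) | fix[multi, "ID"] == ".",
                  paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]),
                  fix[multi, "ID"])
    stop("multi-allelic record(s) not supported: ",
         paste(ids, collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  # ALT allele count per genotype string
  altCount <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }
  ac <- matrix(vapply(gt, altCount, integer(1)), nrow = nrow(gt))
  n_var <- nrow(ac)
  dosage <- matrix(NA_integer_, nrow = length(samples), ncol = n_var,
                   dimnames = list(samples, NULL))
  minor <- major <- character(n_var)
  for (j in seq_len(n_var)) {
    counts <- ac[j, ]
    af_alt <- mean(counts, na.rm = TRUE) / 2
    ref <- fix[j, "REF"]; altj <- alt[j]
    if (is.nan(af_alt)) af_alt <- 0
    if (af_alt < 0.5) {
      minor[j] <- altj; major[j] <- ref
      dosage[, j] <- counts
    } else if (af_alt > 0.5) {
      minor[j] <- ref; major[j] <- altj
      dosage[, j] <- 2L - counts
    } else {  # exact tie: alphabetically first allele is minor
      first <- sort(c(ref, altj))[1]
      minor[j] <- first
      major[j] <- setdiff(c(ref, altj), first)[1]
      dosage[, j] <- if (first == altj) counts else 2L - counts
    }
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  vi <- data.frame(id = ids, chromosome = fix[, "CHROM"],
                   position = as.integer(fix[, "POS"]),
                   minor_allele = minor, major_allele = major,
                   stringsAsFactors = FALSE)
  CohortExperiment(dosage, vi)
}

.readGenotypesTsv <- function(path, variants = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("dosage TSV must start with a 'sample_id' column")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- tab$sample_id
  if (is.null(variants))
    variants <- data.frame(id = colnames(dosage),
                           chromosome = NA_character_,
                           position = NA_integer_,
                           minor_allele = NA_character_,
                           major_allele = NA_character_,
                           stringsAsFactors = FALSE)
  CohortExperiment(dosage, variants)
}

#' Read a phenotype/covariate table
#'
#' Expects a TSV with a `sample_id` column plus any of the standard cohort
#' columns (`fev1`, `fvc`, `physician_copd_dx`, `age`, `sex`, `bmi`,
#' `residence`, lifestyle and nutrient-intake variables, ...). If `fev1`
#' and `fvc` are present, `copd` is derived with [defineCopdStatus()]
#' unless already present.
#'
#' @param path TSV path.
#' @param rule case-definition rule passed to [defineCopdStatus()].
#' @return `data.frame`.
#' @export
readPhenotypes <- function(path, rule = c("spirometry_or_dx",
                                          "spirometry_only")) {
  rule <- match.arg(rule)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("phenotype table needs a 'sample_id' column")
  if (!"copd" %in% names(tab) && all(c("fev1", "fvc") %in% names(tab))) {
    dx <- if ("physician_copd_dx" %in% names(tab))
      tab$physician_copd_dx else FALSE
    tab$copd <- defineCopdStatus(tab$fev1, tab$fvc, dx, rule = rule)
  }
  tab
}

#' Derive COPD case status from spirometry and diagnosis history
#'
#' Applies the GOLD spirometric criterion FEV1/FVC < 0.7. Under
#' `"spirometry_or_dx"` (the default) a participant is a case if either
#' the ratio is below 0.7 or a physician previously diagnosed COPD; under
#' `"spirometry_only"` the ratio alone decides. When spirometry is missing
#' the status is `NA` unless the disjunction is already decided by a
#' positive diagnosis.
#'
#' @param fev1,fvc forced expiratory volume in 1 s and forced vital
#'   capacity, litres (both must be positive where present).
#' @param physician_dx logical, prior physician diagnosis of COPD.
#' @param rule `"spirometry_or_dx"` or `"spirometry_only"`.
#' @return logical vector of case status.
#' @examples
#' defineCopdStatus(2.0, 3.5, FALSE, rule = "spirometry_only")  # TRUE
#' defineCopdStatus(3.0, 3.5, TRUE)                             # TRUE
#' @export
defineCopdStatus <- function(fev1, fvc, physician_dx = FALSE,
                             rule = c("spirometry_or_dx",
                                      "spirometry_only")) {
  rule <- match.arg(rule)
  n <- max(length(fev1), length(fvc), length(physician_dx))
  fev1 <- rep_len(fev1, n); fvc <- rep_len(fvc, n)
  physician_dx <- rep_len(as.logical(physician_dx), n)
  if (any(fev1 <= 0, na.rm = TRUE) || any(fvc <= 0, na.rm = TRUE))
    stop("fev1 and fvc must be positive")
  if (any(fev1 > fvc, na.rm = TRUE))
    warning("some FEV1 values exceed FVC; check units")
  low_ratio <- fev1 / fvc < 0.7
  if (rule == "spirometry_only") low_ratio else low_ratio | physician_dx
}

#' Published lifestyle/dietary cutoffs for high-versus-low dichotomization
#'
#' Cutoffs are known recommended-intake or reference values per exposure
#' (e.g. 0.7 energy-percent of omega-3 fatty acids, 150 min/week of
#' moderate exercise). A value at or above the cutoff is classified
#' "high".
#'
#' @return `data.frame` with columns `exposure` (phenotype column name),
#'   `cutoff` and `unit`.
#' @export
lifestyleCutoffs <- function() {
  data.frame(
    exposure = c("energy_eer_pct", "carb_en_pct", "protein_en_pct",
                 "fat_en_pct", "w3_en_pct", "fiber_g", "vitC_mg",
                 "vitD_ug", "total_polyphenol_mg", "coffee_cups_day",
                 "alcohol_g_day", "exercise_min_week"),
    cutoff = c(100, 70, 15, 15, 0.7, 20, 100, 10, 3220, 1, 20, 150),
    unit = c("% of estimated energy requirement", "En%", "En%", "En%",
             "En%", "g/day", "mg/day", "ug/day", "mg/day", "cups/day",
             "g/day", "min/week"),
    stringsAsFactors = FALSE)
}

#' Dichotomize a lifestyle exposure into low/high
#'
#' Uses the reference cutoff from [lifestyleCutoffs()] when one exists
#' (value >= cutoff is "high"; ties go to "high" since cutoffs are stated
#' as attained recommended intakes). For exposures without a reference
#' value the lowest quartile is "low" (value <= 25th percentile).
#'
#' @param pheno phenotype `data.frame`.
#' @param exposure column name.
#' @param cutoffs cutoff table as returned by [lifestyleCutoffs()].
#' @return factor with levels `c("low", "high")`; `NA` where the exposure
#'   is missing.
#' @examples
#' ph <- data.frame(w3_en_pct = c(0.5, 0.7, 1.2))
#' dichotomizeLifestyle(ph, "w3_en_pct")
#' @export
dichotomizeLifestyle <- function(pheno, exposure,
                                 cutoffs = lifestyleCutoffs()) {
  if (!exposure %in% names(pheno))
    stop("exposure '", exposure, "' not found in phenotype table")
  v <- pheno[[exposure]]
  if (all(is.na(v)))
    stop("exposure '", exposure, "' has no non-missing values")
  hit <- match(exposure, cutoffs$exposure)
  if (!is.na(hit)) {
    high <- v >= cutoffs$cutoff[hit]
  } else {
    q25 <- quantile(v, 0.25, na.rm = TRUE, names = FALSE)
    high <- v > q25
  }
  factor(ifelse(high, "high", "low"), levels = c("low", "high"))
}

#' Standard covariate sets
#'
#' `set1` is the minimal adjustment (residence area, sex, age, BMI);
#' `set2` extends it with occupational exposures, drinking, smoking,
#' exercise, asthma medication and energy intake; `gwas` is the adjustment
#' used in the single-SNP screen. Names refer to phenotype-table columns.
#'
#' @param name one of `"set1"`, `"set2"`, `"gwas"`, `"none"`.
#' @return character vector of covariate column names.
#' @export
covariateSet <- function(name = c("set1", "set2", "gwas", "none")) {
  name <- match.arg(name)
  set1 <- c("residence", "sex", "age", "bmi")
  switch(name,
         none = character(0),
         set1 = set1,
         set2 = c(set1, "chemical_job", "dust_job", "alcohol_g_day",
                  "smoking", "exercise_min_week", "asthma_medication",
                  "energy_eer_pct"),
         gwas = c("age", "sex", "residence", "bmi", "chemical_job",
                  "dust_job", "energy_eer_pct", "alcohol_g_day",
                  "exercise_min_week", "smoking"))
}

#' Write / re-read a cohort as plain TSV files
#'
#' `writeCohort()` writes `dosages.tsv`, `variants.tsv`, `phenotypes.tsv`
#' and, for simulated cohorts, `ground_truth.tsv` into `dir`;
#' `readCohort()` reconstructs the [CohortExperiment]. Dosages and variant
#' metadata round-trip exactly.
#'
#' @param x a [CohortExperiment].
#' @param dir output directory (created if needed).
#' @return `writeCohort()` invisibly returns the file paths;
#'   `readCohort()` returns a [CohortExperiment].
#' @export
writeCohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dosages(x)
  dtab <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                     stringsAsFactors = FALSE)
  paths <- c(dosages = file.path(dir, "dosages.tsv"),
             variants = file.path(dir, "variants.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write.table(dtab, paths["dosages"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(variantInfo(x), paths["variants"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(phenotypes(x), paths["phenotypes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- groundTruth(x)
  if (!is.null(gt)) {
    gt_path <- file.path(dir, "ground_truth.tsv")
    flat <- .flattenGroundTruth(gt)
    write.table(flat, gt_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, ground_truth = gt_path)
  }
  invisible(paths)
}

.flattenGroundTruth <- function(gt) {
  vals <- unlist(gt)
  data.frame(key = names(vals), value = as.character(vals),
             stringsAsFactors = FALSE)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  variants <- read.delim(file.path(dir, "variants.tsv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(chromosome = "character"))
  ce <- .readGenotypesTsv(file.path(dir, "dosages.tsv"), variants)
  ph_path <- file.path(dir, "phenotypes.tsv")
  if (file.exists(ph_path)) {
    ph <- read.delim(ph_path, stringsAsFactors = FALSE)
    ph$sample_id <- as.character(ph$sample_id)
    ce <- CohortExperiment(dosages(ce), variantInfo(ce), ph)
  }
  ce
}
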