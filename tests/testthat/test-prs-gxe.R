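test_that("risk alleles follow the OR direction and PRS sums risk dosages", {
  scan <- data.frame(id = c("a", "b", "c", "d", "e"),
                     or_adj = c(0.7895, 1.269, 1.28, 1.251, 1.281))
  rmap <- riskAlleleMap(scan, scan$id)
  expect_equal(rmap$risk_allele, c("major", rep("minor", 4)))
  # protective SNP with dosage 0 contributes two risk alleles
  d <- rbind(s1 = c(0L, 2L, 1L, 0L, 2L),
             s2 = c(2L, 0L, 0L, 0L, 0L))
  colnames(d) <- scan$id
  prof <- computePrs(d, rmap, cutoffs = c(4, 7))
  # s1 risk dosages: (2, 2, 1, 0, 2) -> 7 -> high
  expect_equal(prof$prs[1], 7)
  expect_equal(as.character(prof$category[1]), "high")
  # s2: all non-risk homozygotes -> 0 -> low
  expect_equal(prof$prs[2], 0)
  expect_equal(as.character(prof$category[2]), "low")
  expect_error(riskAlleleMap(scan, c("a", "zzz")), "zzz")
})

test_that("PRS is invariant under allele relabeling with an updated risk map", {
  withr::with_seed(91, d <- sapply(1:3, function(i)
    simulateGenotypes(0.3, 50)))
  colnames(d) <- c("a", "b", "c"); rownames(d) <- paste0("s", 1:50)
  rmap <- data.frame(id = c("a", "b", "c"),
                     risk_allele = c("minor", "major", "minor"))
  p1 <- computePrs(d, rmap)
  # relabel allele at SNP b: dosage flips, risk allele flips with it
  d2 <- d; d2[, "b"] <- 2L - d[, "b"]
  rmap2 <- rmap; rmap2$risk_allele[2] <- "minor"
  p2 <- computePrs(d2, rmap2)
  expect_identical(p1$prs, p2$prs)
})

test_that("missing-genotype rules: exclusion default, expected-dosage imputation", {
  d <- rbind(s1 = c(1L, NA), s2 = c(2L, 0L), s3 = c(0L, 0L),
             s4 = c(1L, 2L))
  colnames(d) <- c("a", "b")
  rmap <- data.frame(id = c("a", "b"),
                     risk_allele = c("minor", "minor"))
  p_ex <- computePrs(d, rmap, cutoffs = c(0, 2))
  expect_true(is.na(p_ex$prs[1]))
  expect_equal(p_ex$n_missing_snps, c(1L, 0L, 0L, 0L))
  p_im <- computePrs(d, rmap, cutoffs = c(0, 2),
                     missingRule = "impute_expected")
  # risk-allele frequency at b over observed samples = (0+0+2)/6
  expect_equal(p_im$prs[1], 1 + 2 * (2 / 6))
  expect_false(anyNA(p_im$prs))
})

test_that("PRS categories reproduce the published model cutoffs", {
  expect_equal(as.character(prsCategory(c(0, 4, 5, 6, 7, 10), 4, 7)),
               c("low", "low", "middle", "middle", "high", "high"))
  # seven-SNP model: 0-6 / 7-8 / >=9
  expect_equal(as.character(prsCategory(c(6, 7, 9), 6, 9)),
               c("low", "middle", "high"))
  # eight-SNP model: 0-7 / 8-9 / >=10
  expect_equal(as.character(prsCategory(c(7, 9, 10), 7, 10)),
               c("low", "middle", "high"))
  expect_error(prsCategory(1, 4, 5), "cutoffs")
})

test_that("category ORs: reference is 1, null is null, adjustment works", {
  withr::with_seed(101, {
    n <- 3000
    cat <- factor(sample(c("low", "middle", "high"), n, replace = TRUE,
                         prob = c(0.5, 0.35, 0.15)),
                  levels = c("low", "middle", "high"))
    y <- runif(n) < 0.12
  })
  ph <- data.frame(copd = y)
  tab <- adjustedCategoryOr(ph, cat, character(0))
  expect_equal(tab$or[1], 1)
  expect_true(all(tab$ci_lo[-1] < 1 & tab$ci_hi[-1] > 1))

  # constructed confounding: covariate drives both category and outcome
  withr::with_seed(102, {
    n <- 6000
    z <- rnorm(n)
    cat2 <- factor(ifelse(z + rnorm(n) > 0.8, "high",
                          ifelse(z + rnorm(n) > 0, "middle", "low")),
                   levels = c("low", "middle", "high"))
    y2 <- runif(n) < plogis(-2 + 1.0 * z)   # no true category effect
  })
  ph2 <- data.frame(copd = y2, z = z)
  crude <- adjustedCategoryOr(ph2, cat2, character(0))
  adj <- adjustedCategoryOr(ph2, cat2, "z")
  expect_gt(crude$or[crude$category == "high"], 1.3)  # confounded
  expect_lt(abs(log(adj$or[adj$category == "high"])), 0.3)
})

test_that("category OR recovery on prevalence-calibrated five-SNP cohorts", {
  ors <- vapply(1:25, function(s) {
    ce <- simulateCohort(fiveSnpPrsConfig(6000, log(1.4), log(2.2)),
                         seed = 400 + s)
    prof <- computePrs(ce, fiveSnpRiskMap(), c(4, 7))
    tab <- adjustedCategoryOr(phenotypes(ce), prof$category,
                              covariateSet("set1"))
    tab$or[tab$category == "high"]
  }, numeric(1))
  g <- geoMeanSummary(ors)
  expect_lt(abs(g$mean_log - log(2.2)), 3 * g$se_log)
})

test_that("interaction test flags degenerate designs and detects real G x E", {
  ph <- data.frame(copd = rep(c(TRUE, FALSE), 50))
  cat <- factor(rep(c("low", "high"), each = 50),
                levels = c("low", "middle", "high"))
  expect_error(interactionTest(ph, cat, factor(rep("low", 100),
                                               levels = c("low", "high")),
                               character(0)),
               "constant")
  # strong planted interaction is detected
  ps <- vapply(1:5, function(s) {
    cfg <- fiveSnpPrsConfig(6000, NULL, NULL,
      gxe = list(exposure = "w3_en_pct", pHigh = 0.5,
                 logOrMidLow = log(1.6), logOrHighLow = log(3.5),
                 logOrMidHigh = 0, logOrHighHigh = 0))
    ce <- simulateCohort(cfg, seed = 500 + s)
    ph <- phenotypes(ce)
    prof <- computePrs(ce, fiveSnpRiskMap(), c(4, 7))
    ex <- dichotomizeLifestyle(ph, "w3_en_pct")
    interactionTest(ph, prof$category, ex, character(0))$p_interaction
  }, numeric(1))
  expect_gte(sum(ps < 0.05), 3)
})

test_that("stratified ORs equal the full-interaction model on a saturated toy", {
  withr::with_seed(111, {
    n <- 4000
    cat <- factor(sample(c("low", "middle", "high"), n, TRUE,
                         c(0.4, 0.4, 0.2)),
                  levels = c("low", "middle", "high"))
    ex <- factor(sample(c("low", "high"), n, TRUE),
                 levels = c("low", "high"))
    lp <- -2 + 0.4 * (cat == "middle") + 0.9 * (cat == "high") +
      0.3 * (ex == "high") - 0.5 * (cat == "high") * (ex == "high")
    y <- runif(n) < plogis(lp)
  })
  ph <- data.frame(copd = y)
  so <- stratifiedOr(ph, cat, ex, character(0))
  # oracle: one saturated glm with full category x exposure interaction
  fit <- glm(y ~ cat * ex, family = binomial())
  b <- coef(fit)
  expect_equal(log(so$low$or[so$low$category == "high"]),
               unname(b["cathigh"]), tolerance = 1e-6)
  expect_equal(log(so$high$or[so$high$category == "high"]),
               unname(b["cathigh"] + b["cathigh:exhigh"]),
               tolerance = 1e-6)
  expect_equal(so$low$or[1], 1)
  expect_false(attr(so$low, "small_stratum"))
})

test_that("dose-response: additive generation yields ordered category ORs", {
  ok <- vapply(1:5, function(s) {
    ce <- simulateCohort(fiveSnpPrsConfig(8840, log(1.5), log(2.3)),
                         seed = 600 + s)
    prof <- computePrs(ce, fiveSnpRiskMap(), c(4, 7))
    tab <- adjustedCategoryOr(phenotypes(ce), prof$category,
                              covariateSet("set1"))
    or_m <- tab$or[tab$category == "middle"]
    or_h <- tab$or[tab$category == "high"]
    or_h >= or_m && or_m >= 1
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("adjusted means reduce to raw means without covariates and flag nulls", {
  withr::with_seed(121, {
    grp <- factor(rep(c("a", "b", "c"), each = 40))
    yv <- rnorm(120, mean = c(1, 1, 1)[as.integer(grp)])
  })
  am <- adjustedMeans(yv, grp)
  raw <- tapply(yv, grp, mean)
  expect_equal(am$means$emmean,
               as.numeric(raw[as.character(am$means$group)]),
               tolerance = 1e-12)
  expect_true(all(am$contrasts$p.value > 0.05))
  # a real group effect is recovered after covariate adjustment
  withr::with_seed(122, {
    n <- 2000
    z <- rnorm(n)
    grp2 <- factor(ifelse(rnorm(n) + z > 0.5, "high", "low"))
    y2 <- 0.8 - 0.05 * (grp2 == "high") + 0.02 * z + rnorm(n, 0, 0.05)
  })
  am2 <- adjustedMeans(y2, grp2, data.frame(z = z), "z")
  diff <- am2$means$emmean[am2$means$group == "low"] -
    am2$means$emmean[am2$means$group == "high"]
  expect_lt(abs(diff - 0.05), 0.01)
  expect_true(any(am2$contrasts$p.value < 0.001))
})
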