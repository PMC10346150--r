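test_that("score statistics match closed forms and sum to zero", {
  ph <- data.frame(copd = rep(c(TRUE, FALSE), c(50, 50)))
  s <- scoreStatistics(ph, character(0))
  expect_equal(s, rep(c(0.5, -0.5), c(50, 50)))
  ph2 <- data.frame(copd = rep(c(TRUE, FALSE), c(99, 901)))
  s2 <- scoreStatistics(ph2, character(0))
  expect_equal(unique(round(s2, 6)), c(0.901, -0.099))
  # MLE score equation: residuals sum to zero with covariates too
  ce <- simulateCohort(simulationConfig(nSamples = 400), seed = 2)
  s3 <- scoreStatistics(phenotypes(ce), covariateSet("set1"))
  expect_lt(abs(sum(s3)), 1e-8)
  expect_true(all(s3 > -1 & s3 < 1))
})

test_that("cell tables label by score-sum sign with ties and empties low", {
  # 9-sample toy on one SNP, hand-computed
  d <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L), ncol = 1,
              dimnames = list(paste0("s", 1:9), "v"))
  scores <- c(-.2, -.2, .1, .3, .2, -.1, -.25, .25, 0)
  cells <- buildCells(scores, d, "v", 1:9)
  # sums: cell0 = -0.3 low, cell1 = 0.4 high, cell2 = 0 tie -> low
  expect_equal(cells$label, c("low", "high", "low"))
  expect_equal(cells$count, c(3L, 3L, 3L))
  # all-negative scores: every non-empty cell low
  cells2 <- buildCells(rep(-1, 9), d, "v", 1:9)
  expect_true(all(cells2$label == "low"))
  # missing genotype excluded and counted
  d[1, 1] <- NA
  cells3 <- buildCells(scores, d, "v", 1:9)
  expect_equal(cells3$n_excluded, 1)
  expect_equal(cells3$count[1], 2L)
})

test_that("balanced accuracy follows (sens + spec)/2 with unseen cells low", {
  # two-cell perfect predictor
  d <- matrix(rep(c(0L, 2L), each = 20), ncol = 1,
              dimnames = list(paste0("s", 1:40), "v"))
  y <- rep(c(FALSE, TRUE), each = 20)
  s <- ifelse(y, 0.9, -0.1)
  cells <- buildCells(s, d, "v", 1:40)
  expect_equal(balancedAccuracy(cells, d, y, 1:40), 1.0)
  # all-low predictor: (0 + 1)/2
  cells_low <- buildCells(rep(-1, 40), d, "v", 1:40)
  expect_equal(balancedAccuracy(cells_low, d, y, 1:40), 0.5)
  # confusion (TP 30, FN 10, TN 50, FP 10) -> (0.75 + 0.8333)/2
  d2 <- matrix(rep(c(2L, 2L, 0L, 0L), c(30, 10, 50, 10)), ncol = 1,
               dimnames = list(paste0("s", 1:100), "v"))
  y2 <- rep(c(TRUE, FALSE, FALSE, TRUE), c(30, 10, 50, 10))
  cells2 <- list(label = c("low", "empty", "high"), snps = "v")
  expect_equal(balancedAccuracy(cells2, d2, y2, 1:100),
               (0.75 + 50 / 60) / 2, tolerance = 1e-12)
  expect_error(balancedAccuracy(cells2, d2, rep(TRUE, 100), 1:100),
               "cases and controls")
})

test_that("sign test reproduces the exact binomial tail", {
  expect_equal(signTest(10), 1 / 1024)
  expect_equal(signTest(9), 11 / 1024)
  expect_equal(signTest(5), 638 / 1024)
  expect_equal(signTest(0), 1)
})

test_that("gmdrSearch equals the naive exhaustive oracle fold by fold", {
  withr::with_seed(81, {
    reps <- lapply(1:4, function(r) {
      n <- sample(120:200, 1)
      m <- sample(4:6, 1)
      d <- sapply(seq_len(m), function(j)
        simulateGenotypes(runif(1, 0.2, 0.5), n))
      colnames(d) <- paste0("g", seq_len(m))
      rownames(d) <- paste0("s", seq_len(n))
      y <- runif(n) < plogis(-1 + 0.8 * d[, 1] * (d[, 2] > 0))
      list(d = d, y = y)
    })
  })
  for (rep in reps) {
    ph <- data.frame(copd = rep$y)
    folds <- withr::with_seed(5, sample(rep_len(1:5, nrow(rep$d))))
    scores <- scoreStatistics(ph, character(0))
    for (k in 1:3) {
      res <- gmdrSearch(rep$d, character(0), colnames(rep$d),
                        kRange = k, nFolds = 5, pheno = ph,
                        folds = folds)
      pf <- gmdrFolds(res)
      for (f in 1:5) {
        oc <- oracleGmdrFold(rep$d, rep$y, scores, colnames(rep$d), k,
                             folds, f)
        expect_identical(pf$snps[pf$fold == f], oc$snps)
        expect_equal(pf$trba[pf$fold == f], oc$trba, tolerance = 1e-12)
        expect_equal(pf$teba[pf$fold == f], oc$teba, tolerance = 1e-12)
      }
    }
  }
})

test_that("planted epistasis is detected; permuted outcomes are not", {
  off <- rep(0, 9); off[c(1, 5, 9)] <- 1.2
  hits <- 0; cvcs <- integer(0)
  for (s in 1:6) {
    cfg <- simulationConfig(nSamples = 2000,
      variants = data.frame(id = paste0("v", 1:5),
                            maf = c(0.3, 0.3, 0.25, 0.35, 0.4),
                            log_or = 0),
      covariateEffects = c(sex_male = log(1.5)),
      epistasis = list(snps = c("v1", "v2"), offsets = off),
      targetPrevalence = 0.2)
    ce <- simulateCohort(cfg, seed = 200 + s)
    res <- gmdrSearch(ce, covariateSet("set1"), paste0("v", 1:5),
                      kRange = 2, seed = s)
    mod <- gmdrModels(res)
    if (mod$snps == "v1,v2") hits <- hits + 1
    cvcs <- c(cvcs, mod$cvc)
  }
  expect_gte(hits, 5)
  expect_gte(mean(cvcs >= 9), 0.5)

  # permuted outcome: TEBA hovers around chance
  tebas <- vapply(1:5, function(s) {
    ce <- simulateCohort(simulationConfig(nSamples = 2000,
      variants = data.frame(id = paste0("v", 1:4),
                            maf = rep(0.3, 4), log_or = 0),
      targetPrevalence = 0.2), seed = 300 + s)
    gmdrModels(gmdrSearch(ce, character(0), paste0("v", 1:4),
                          kRange = 2, seed = s))$teba
  }, numeric(1))
  expect_gt(mean(tebas), 0.42)
  expect_lt(mean(tebas), 0.58)
})

test_that("gmdrSearch is reproducible and selection applies both criteria", {
  ce <- simulateCohort(simulationConfig(nSamples = 500), seed = 12)
  cand <- variantInfo(ce)$id[c(2, 5, 8, 10)]
  r1 <- gmdrSearch(ce, covariateSet("set1"), cand, kRange = 1:2,
                   seed = 99)
  r2 <- gmdrSearch(ce, covariateSet("set1"), cand, kRange = 1:2,
                   seed = 99)
  expect_identical(gmdrModels(r1), gmdrModels(r2))
  expect_identical(gmdrFolds(r1), gmdrFolds(r2))

  fake <- new("GMDRResult", models = data.frame(
    k = c(3L, 5L), snps = c("a,b,c", "a,b,c,d,e"),
    trba = c(0.6, 0.62), teba = c(0.6, 0.6), cvc = c(10L, 10L),
    sign_test_p = c(1e-4, 1e-4), n_folds = 10L),
    perFold = data.frame(), seed = 1L)
  best <- selectBestModel(fake, signAlpha = 0.001, minCvc = 10)
  expect_equal(best$k, 3)  # TEBA tie goes to the smaller k
  none <- selectBestModel(new("GMDRResult", models = data.frame(
    k = 1L, snps = "a", trba = 0.5, teba = 0.5, cvc = 4L,
    sign_test_p = 0.6, n_folds = 10L), perFold = data.frame(),
    seed = 1L))
  expect_equal(nrow(none), 0)
  expect_match(attr(none, "reasons"), "cvc=4")
})
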