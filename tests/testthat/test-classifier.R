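test_that("a separable gene yields AUC 1 and the top coefficient", {
  set.seed(2)
  z <- matrix(rnorm(30 * 40), 30, 40,
              dimnames = list(sprintf("G%02d", 1:30),
                              sprintf("S%02d", 1:40)))
  z["G07", 1:20] <- z["G07", 1:20] + 10
  res <- fitClassifier(z, positive = colnames(z)[1:20],
                       negative = colnames(z)[21:40], seed = 1)
  expect_equal(pooledAUC(res), 1.0)
  expect_equal(topFeatures(res, 1)$gene_id, "G07")
  # k = gene count returns a permutation of all genes
  expect_setequal(topFeatures(res, 30)$gene_id, rownames(z))
  expect_error(topFeatures(res, 0), "positive")
})

test_that("classification is deterministic under a fixed seed", {
  set.seed(5)
  z <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(sprintf("G%02d", 1:20),
                              sprintf("S%02d", 1:30)))
  a <- fitClassifier(z, colnames(z)[1:15], colnames(z)[16:30], seed = 9)
  b <- fitClassifier(z, colnames(z)[1:15], colnames(z)[16:30], seed = 9)
  expect_identical(a@folds, b@folds)
  expect_identical(classifierCoefficients(a), classifierCoefficients(b))
  expect_identical(pooledAUC(a), pooledAUC(b))
  # pooled AUC is invariant to monotone transforms of the scores
  expect_equal(unname(pooledAUC(a)),
               phipkit:::rankAUC(exp(a@scores), a@labels))
})

test_that("label permutation drives the AUC to chance", {
  set.seed(31)
  z <- matrix(rnorm(40 * 60), 40, 60,
              dimnames = list(sprintf("G%02d", 1:40),
                              sprintf("S%02d", 1:60)))
  z["G01", 1:30] <- z["G01", 1:30] + 5  # real signal ...
  aucs <- vapply(1:10, function(s) {
    perm <- sample(colnames(z))          # ... destroyed by permutation
    pooledAUC(fitClassifier(z, perm[1:30], perm[31:60], seed = s))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("undefined z entries are imputed neutrally", {
  z <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("G%02d", 1:10),
                              sprintf("S%02d", 1:20)))
  z[3, ] <- NA  # a zero-variance reference gene
  res <- fitClassifier(z, colnames(z)[1:10], colnames(z)[11:20], seed = 2)
  expect_equal(unname(classifierCoefficients(res)["G03"]), 0)
})

test_that("precondition violations are named errors", {
  z <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(sprintf("G%d", 1:5), sprintf("S%02d", 1:12)))
  expect_error(fitClassifier(z, colnames(z)[1:12], character(), seed = 1),
               "both classes")
  expect_error(fitClassifier(z, colnames(z)[1:2], colnames(z)[3:12],
                             folds = 5, seed = 1), "more folds")
  expect_error(fitClassifier(z, colnames(z)[1:6], colnames(z)[6:12],
                             seed = 1), "overlap")
})

test_that("subgroup classifications match the direct fit and skip empties", {
  cfg <- simulationConfig(nGenes = 25, peptidesPerGene = 2,
                          nPreControls = 10, nComparators = 12, nCases = 12,
                          nMockIP = 3, depthMean = 3e4, seed = 17,
                          plantedAntigens = list(
                            plantedAntigen("GENE0004", targetCohorts = "case",
                                           prevalence = 0.7,
                                           effectMultiplier = 60)))
  gss <- normalizePhip(simulateCohort(cfg))
  cases <- selectSamples(gss, "case")
  comps <- selectSamples(gss, "comparator")
  defs <- list(full = list(positive = cases, negative = comps),
               empty = list(positive = character(), negative = comps))
  expect_warning(res <- subgroupClassifications(gss, defs, seed = 3),
                 "empty class")
  expect_equal(attr(res, "skipped"), "empty")
  direct <- fitClassifier(gss, cases, comps, seed = 3, contrast = "full")
  expect_equal(pooledAUC(res$full), pooledAUC(direct))
  expect_equal(classifierCoefficients(res$full),
               classifierCoefficients(direct))
})

test_that("a phenotype-specific antigen separates only its phenotype", {
  cfg <- simulationConfig(nGenes = 30, peptidesPerGene = 2,
                          nPreControls = 10, nComparators = 20, nCases = 40,
                          nMockIP = 4, depthMean = 5e4, seed = 23,
                          phenotypeDefs = c(cardio = 0.5, gi = 0.5),
                          plantedAntigens = list(
                            plantedAntigen("GENE0011", targetCohorts = "case",
                                           prevalence = 0.9,
                                           effectMultiplier = 80,
                                           restrictToPhenotype = "cardio")))
  gss <- normalizePhip(simulateCohort(cfg))
  comps <- selectSamples(gss, "comparator")
  defs <- list(
    cardio = list(positive = selectSamples(gss, "case", "cardio"),
                  negative = comps),
    gi = list(positive = selectSamples(gss, "case", "gi"), negative = comps))
  res <- subgroupClassifications(gss, defs, folds = 3, seed = 4)
  expect_gt(pooledAUC(res$cardio), pooledAUC(res$gi))
})
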