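test_that("gene collapsing sums peptides and pseudocounts every gene", {
  gss <- collapseToGenes(tinyPhipSet())
  g <- geneMatrix(gss)
  expect_equal(g["GA", "mock1"], 15.5)   # 10 + 5 + 0.5
  expect_equal(unname(g["GB", ]), rep(0.5, 5))  # zero-read gene included
  expect_true(all(g >= 0.5))
  # single-peptide gene: collapse is counts + 0.5 elementwise
  expect_equal(g["GB", "case1"], 0 + 0.5)
})

test_that("percent normalization sums to 100 and scales symmetrically", {
  cts <- matrix(c(0L, 0L), 2, 1, dimnames = list(c("GA_p1", "GB_p1"), "m"))
  lib <- data.frame(peptide_id = c("GA_p1", "GB_p1"), gene_id = c("GA", "GB"),
                    protein_name = c("GA", "GB"), start_pos = 0L,
                    aa_seq = "ACDE")
  sheet <- data.frame(sample_id = "m", role = "mock_ip")
  gss <- percentNormalize(collapseToGenes(
    PhIPSet(cts, lib, sheet), pseudocount = 0.5))
  expect_equal(unname(percentMatrix(gss)[, 1]), c(50, 50))  # {0.5, 0.5}

  cts[1, 1] <- 1L  # gene totals {1.5, 0.5} -> {75, 25}
  gss <- percentNormalize(collapseToGenes(PhIPSet(cts, lib, sheet)))
  expect_equal(unname(percentMatrix(gss)[, 1]), c(75, 25))

  gss <- percentNormalize(collapseToGenes(tinyPhipSet()))
  expect_true(all(abs(colSums(percentMatrix(gss)) - 100) < 1e-9))
})

test_that("fold change divides by the mock-IP mean percentage", {
  gss <- computeFoldChange(percentNormalize(collapseToGenes(tinyPhipSet())))
  fc <- fcMatrix(gss)
  pct <- percentMatrix(gss)
  expect_equal(fc, pct / pct[, "mock1"])   # single mock well
  # a sample identical to the single mock-IP sample has FC 1 everywhere
  cts <- phipCounts(tinyPhipSet())
  cts[, "case1"] <- cts[, "mock1"]
  gss2 <- computeFoldChange(percentNormalize(collapseToGenes(
    tinyPhipSet(cts))))
  expect_equal(unname(fcMatrix(gss2)[, "case1"]), c(1, 1))
  # no mock-IP wells is a precondition failure
  se <- gssFromFC(matrix(1, 1, 3, dimnames = list("g", c("a", "b", "c"))),
                  roles = rep("case", 3))
  expect_error(computeFoldChange(se), "mock_ip")
})

test_that("z-scores center on the reference and flag zero-variance genes", {
  fc <- matrix(c(1, 1, 1, 11,
                 1, 2, 3, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("r1", "r2", "r3", "s")))
  gss <- computeZScores(gssFromFC(fc, c(rep("pre_control", 3), "case")))
  z <- zMatrix(gss); zd <- zDefined(gss)
  expect_false(zd["g1", "s"])           # sd = 0: undefined, not infinite
  expect_true(is.na(z["g1", "s"]))
  expect_equal(z["g2", "s"], 0)         # equals reference mean -> z = 0
  expect_error(
    computeZScores(gssFromFC(fc[, 1:3], rep("pre_control", 3)),
                   referenceRole = "case"),
    ">= 3")
})

test_that("leave-one-out z-scores match a from-scratch oracle", {
  set.seed(77)
  fc <- matrix(rlnorm(8 * 9), 8, 9,
               dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:9)))
  roles <- c(rep("pre_control", 5), rep("case", 4))
  gss <- computeZScores(gssFromFC(fc, roles))
  zo <- looZOracle(fc, refCols = 1:5)
  expect_equal(zMatrix(gss), zo, tolerance = 1e-10)
})

test_that("calls use inclusive thresholds and are independent", {
  fc <- matrix(c(5.0, 4.999, 0.5), 1, 3,
               dimnames = list("g", c("a", "b", "c")))
  gss <- gssFromFC(fc, roles = rep("case", 3))
  assays(gss)$zscore <- matrix(c(2, 7, NA), 1, 3, dimnames = dimnames(fc))
  assays(gss)$zdefined <- matrix(c(TRUE, TRUE, FALSE), 1, 3,
                                 dimnames = dimnames(fc))
  gss <- callReactivity(gss)
  expect_true(enrichedCalls(gss)["g", "a"])      # FC = 5.0 inclusive
  expect_false(enrichedCalls(gss)["g", "b"])     # 4.999 not enriched
  expect_true(positiveCalls(gss)["g", "b"])      # z = 7 positive anyway
  expect_false(positiveCalls(gss)["g", "c"])     # undefined z never positive
})

test_that("the pipeline is invariant to a sample's sequencing depth", {
  # exact at the percent stage without pseudocount
  pset <- tinyPhipSet()
  cts <- phipCounts(pset)
  cts2 <- cts
  cts2[, "case1"] <- cts2[, "case1"] * 7L
  p1 <- percentNormalize(collapseToGenes(tinyPhipSet(cts), pseudocount = 0))
  p2 <- percentNormalize(collapseToGenes(tinyPhipSet(cts2), pseudocount = 0))
  expect_equal(percentMatrix(p1)[, "case1"], percentMatrix(p2)[, "case1"],
               tolerance = 1e-12)
  # with the 0.5 pseudocount, approximate at realistic sequencing depth,
  # and the sample's calls are unchanged
  pset <- simulateCohort(smallNullConfig(seed = 3, nGenes = 20))
  cts <- phipCounts(pset)
  s <- "Case001"
  cts2 <- cts; cts2[, s] <- cts2[, s] * 5L
  g1 <- normalizePhip(PhIPSet(cts, peptideLibrary(pset), sampleSheet(pset)))
  g2 <- normalizePhip(PhIPSet(cts2, peptideLibrary(pset), sampleSheet(pset)))
  expect_equal(percentMatrix(g1)[, s], percentMatrix(g2)[, s],
               tolerance = 1e-3)
  expect_identical(enrichedCalls(g1)[, s], enrichedCalls(g2)[, s])
  expect_identical(positiveCalls(g1)[, s], positiveCalls(g2)[, s])
})

test_that("peptide profiles report reads-per-100k and focality", {
  pset <- tinyPhipSet()
  prof <- peptideProfile(pset, "GA", c("pre1", "case1"))
  expect_equal(prof$peptide_id, c("GA_p1", "GA_p2"))
  expect_true(all(diff(prof$start_pos) > 0))
  # hand-computed reads per 100,000: totals pre1 = 3, case1 = 12
  expect_equal(prof$mean_rp100k,
               c(mean(c(2 / 3, 8 / 12)) * 1e5, mean(c(1 / 3, 4 / 12)) * 1e5))
  expect_equal(attr(prof, "focality"), 2 / 3)
  # all reads on one peptide -> focality 1; uniform over k -> 1/k
  cts <- phipCounts(pset); cts["GA_p2", ] <- 0L
  expect_equal(attr(peptideProfile(tinyPhipSet(cts), "GA", "case1"),
                    "focality"), 1.0)
  cts["GA_p2", ] <- cts["GA_p1", ]
  expect_equal(attr(peptideProfile(tinyPhipSet(cts), "GA", "case1"),
                    "focality"), 0.5)
  expect_error(peptideProfile(pset, "NOPE", "case1"), "unknown gene")
})

test_that("positivity fractions recover planted prevalence", {
  gss <- normalizePhip(tinyPhipSet())
  expect_equal(positivityFraction(gss, "GB", cohort = "case"), 0)
  expect_error(positivityFraction(gss, "GB", cohort = "comparator"),
               "empty cohort")
  cfg <- simulationConfig(nGenes = 30, peptidesPerGene = 2,
                          nPreControls = 12, nComparators = 40, nCases = 60,
                          nMockIP = 4, depthMean = 5e4, seed = 14,
                          plantedAntigens = list(
                            plantedAntigen("GENE0009", prevalence = 0.3,
                                           effectMultiplier = 100)))
  gss <- normalizePhip(simulateCohort(cfg))
  frac <- positivityFraction(gss, "GENE0009")
  se <- sqrt(0.3 * 0.7 / 100)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("re-running the chain reproduces identical outputs", {
  pset <- tinyPhipSet()
  g1 <- normalizePhip(pset)
  g2 <- normalizePhip(pset)
  expect_identical(assays(g1), assays(g2))
})
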