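test_that("KS statistic matches brute-force ECDF evaluation", {
  expect_equal(ksTwoSample(c(1, 2, 3), c(4, 5, 6))$D, 1.0)  # disjoint
  x <- c(2, 5, 9, 9)
  expect_equal(ksTwoSample(x, x)$D, 0)                       # identical
  set.seed(12)
  for (i in 1:50) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:10, n1, replace = TRUE)  # integer lists: ties exercised
    y <- sample(1:10, n2, replace = TRUE)
    for (alt in c("two_sided", "greater")) {
      got <- ksTwoSample(x, y, alt)
      expect_equal(got$D, ksOracle(x, y, alt), info = alt)
    }
    # one-sided D never exceeds two-sided D
    expect_lte(ksTwoSample(x, y, "greater")$D, ksTwoSample(x, y)$D)
    # two-sided D is symmetric and monotone-transform invariant
    expect_equal(ksTwoSample(x, y)$D, ksTwoSample(y, x)$D)
    expect_equal(ksTwoSample(exp(x), exp(y))$D, ksTwoSample(x, y)$D)
  }
  expect_error(ksTwoSample(1, c(1, 2)), "n >= 2")
})

test_that("the one-sided direction is 'greater in the first group'", {
  set.seed(3)
  lo <- rnorm(30); hi <- rnorm(30) + 3
  up <- ksTwoSample(hi, lo, "greater")
  down <- ksTwoSample(lo, hi, "greater")
  expect_lt(up$p_value, 0.001)   # hi really is greater
  expect_gt(down$p_value, 0.5)   # wrong direction: no evidence
})

test_that("antigen scans rank a strong planted case antigen first", {
  cfg <- simulationConfig(nGenes = 40, peptidesPerGene = 2,
                          nPreControls = 10, nComparators = 15, nCases = 15,
                          nMockIP = 4, depthMean = 5e4, seed = 41,
                          plantedAntigens = list(
                            plantedAntigen("GENE0013", targetCohorts = "case",
                                           prevalence = 0.8,
                                           effectMultiplier = 60)))
  gss <- normalizePhip(simulateCohort(cfg))
  scan <- antigenScan(gss, selectSamples(gss, "case"),
                      selectSamples(gss, "comparator"),
                      alternative = "greater")
  expect_equal(scan$gene_id[which.min(scan$p_value)], "GENE0013")
  expect_true(all(scan$D >= 0 & scan$D <= 1))
  expect_true(all(scan$p_value >= 0 & scan$p_value <= 1))
  # BH adjustment is opt-in
  expect_false("p_adj" %in% colnames(scan))
  scan2 <- antigenScan(gss, selectSamples(gss, "case"),
                       selectSamples(gss, "comparator"), adjust = TRUE)
  expect_equal(scan2$p_adj, p.adjust(scan2$p_value, "BH"))
  # overlapping selectors are a precondition failure
  expect_error(antigenScan(gss, selectSamples(gss, "case"),
                           selectSamples(gss, c("case", "comparator"))),
               "overlap")
})

test_that("phenotype scans run one contrast per label", {
  cfg <- simulationConfig(nGenes = 15, peptidesPerGene = 2,
                          nPreControls = 6, nComparators = 10, nCases = 20,
                          nMockIP = 3, depthMean = 2e4, seed = 6,
                          phenotypeDefs = c(cardiopulmonary = 0.5,
                                            neuro = 0.4, gi = 0.5,
                                            musculoskeletal = 0.4,
                                            upper_resp = 0.3, severe = 0.3))
  gss <- normalizePhip(simulateCohort(cfg))
  scans <- phenotypeScan(gss)
  expect_equal(length(scans), 6)
  pm <- attr(scans, "p_matrix")
  expect_equal(dim(pm), c(15, 6))
  expect_true(all(scans$gi$alternative == "greater"))
  expect_true(all(scans$gi$n2 == 10))   # comparator cohort size
})

test_that("shared-antigen tabulation recovers planted cohort structure", {
  planted <- sprintf("GENE%04d", 1:8)
  cfg <- simulationConfig(nGenes = 60, peptidesPerGene = 2,
                          nPreControls = 10, nComparators = 15, nCases = 15,
                          nMockIP = 4, depthMean = 5e4, seed = 51,
                          plantedAntigens = lapply(planted, plantedAntigen,
                            prevalence = 0.6, effectMultiplier = 60))
  gss <- normalizePhip(simulateCohort(cfg))
  tab <- sharedAntigens(gss, planted, k = 8)
  expect_true(all(tab$present_in_case))
  expect_true(all(tab$present_in_comparator))
  expect_false(any(tab$present_in_pre))
  expect_equal(unname(attr(tab, "summary")["n_in_both_post"]), 8)
  # k beyond the gene count truncates without error
  tab2 <- sharedAntigens(gss, rownames(gss), k = 1000)
  expect_equal(nrow(tab2), 60)
  expect_error(sharedAntigens(gss, planted, k = 0), "k must be")
})
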