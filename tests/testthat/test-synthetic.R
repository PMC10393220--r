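test_that("library generation respects counts, lengths and tiling", {
  cfg <- simulationConfig(nGenes = 3, peptidesPerGene = 2, seed = 11)
  lib <- generateLibrary(cfg)
  expect_equal(nrow(lib), 6)
  expect_equal(length(unique(lib$gene_id)), 3)
  expect_true(all(table(lib$gene_id) == 2))
  expect_true(all(nchar(lib$aa_seq) == 49))
  # start positions increase within each gene
  for (g in unique(lib$gene_id))
    expect_true(all(diff(lib$start_pos[lib$gene_id == g]) > 0))
  # determinism
  expect_identical(lib, generateLibrary(cfg))
})

test_that("cohort simulation is deterministic and structurally sound", {
  cfg <- smallNullConfig(seed = 21, nGenes = 20)
  p1 <- simulateCohort(cfg)
  p2 <- simulateCohort(cfg)
  expect_identical(phipCounts(p1), phipCounts(p2))
  expect_identical(sampleSheet(p1), sampleSheet(p2))
  expect_identical(groundTruth(p1), groundTruth(p2))
  cts <- phipCounts(p1)
  expect_true(all(cts >= 0))
  expect_true(all(cts == round(cts)))
  expect_equal(sum(sampleRoles(p1) == "mock_ip"), 4)
  # null simulation carries an empty ground truth, not an error
  expect_equal(nrow(groundTruth(p1)), 0)
})

test_that("a fully penetrant strong antigen lifts every case above the
           control background median", {
  cfg <- simulationConfig(nGenes = 30, peptidesPerGene = 2,
                          nPreControls = 10, nComparators = 3, nCases = 12,
                          nMockIP = 3, depthMean = 5e4, seed = 33,
                          plantedAntigens = list(
                            plantedAntigen("GENE0005", targetCohorts = "case",
                                           prevalence = 1,
                                           effectMultiplier = 50)))
  pset <- simulateCohort(cfg)
  cts <- phipCounts(pset)
  gid <- peptideLibrary(pset)$gene_id
  geneProp <- rowsum(cts, gid)
  geneProp <- sweep(geneProp, 2, colSums(cts), "/")
  roles <- sampleRoles(pset)
  caseP <- geneProp["GENE0005", roles == "case"]
  ctrlP <- geneProp["GENE0005", roles == "pre_control"]
  expect_true(all(caseP > median(ctrlP)))
  gt <- groundTruth(pset)
  expect_true(all(gt$sample_id %in% names(roles)[roles == "case"]))
  expect_true(all(gt$reactive))
})

test_that("realized prevalence stays within binomial sampling error", {
  for (seed in c(1, 2, 3)) {
    cfg <- simulationConfig(nGenes = 10, peptidesPerGene = 2,
                            nPreControls = 5, nComparators = 40, nCases = 60,
                            nMockIP = 3, depthMean = 1e4, seed = seed,
                            plantedAntigens = list(
                              plantedAntigen("GENE0002", prevalence = 0.3,
                                             effectMultiplier = 20)))
    pset <- simulateCohort(cfg)
    gt <- groundTruth(pset)
    n <- nrow(gt)
    se <- sqrt(0.3 * 0.7 / n)
    expect_lt(abs(mean(gt$reactive) - 0.3), 3 * se)
  }
})

test_that("phenotype restriction confines reactivity to flagged cases", {
  cfg <- simulationConfig(nGenes = 10, peptidesPerGene = 2,
                          nPreControls = 4, nComparators = 4, nCases = 40,
                          nMockIP = 2, depthMean = 1e4, seed = 9,
                          phenotypeDefs = c(gi = 0.5),
                          plantedAntigens = list(
                            plantedAntigen("GENE0001", targetCohorts = "case",
                                           prevalence = 1,
                                           effectMultiplier = 10,
                                           restrictToPhenotype = "gi")))
  pset <- simulateCohort(cfg)
  gt <- groundTruth(pset)
  flagged <- sampleSheet(pset)
  flagged <- flagged$sample_id[flagged$pheno_gi %in% TRUE]
  expect_true(all(gt$sample_id %in% flagged))
})

test_that("invalid configurations are rejected up front", {
  expect_error(simulationConfig(nGenes = 0), "nGenes")
  expect_error(simulationConfig(depthMean = -1), "depthMean")
  expect_error(
    simulationConfig(plantedAntigens = list(
      plantedAntigen("G1", prevalence = 1.5, effectMultiplier = 2))),
    "prevalence")
  expect_error(
    simulationConfig(plantedAntigens = list(
      plantedAntigen("G1", prevalence = 0.5, effectMultiplier = 0.5))),
    "effect_multiplier")
  cfg <- smallNullConfig(seed = 1, nGenes = 5)
  cfg@plantedAntigens <- list(plantedAntigen("NOPE", prevalence = 0.5,
                                             effectMultiplier = 5))
  expect_error(simulateCohort(cfg), "not in library")
})
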