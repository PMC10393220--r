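#' Simulation configuration for synthetic PhIP-Seq cohorts
#'
#' Defines a seeded synthetic study with the statistical structure the
#' analysis chain assumes: a shared heavy-tailed background of nonspecific
#' phage binding (a single Dirichlet draw per library, correlated across
#' samples — fold-change over mock IP is only meaningful because background
#' is shared), per-sample multiplicative lognormal noise, negative-binomial
#' sequencing depth, and planted antigen reactivities with configurable
#' prevalence and effect size. Cohort-size defaults follow the long COVID
#' study design the package targets: 121 cases, 64 convalescent comparators,
#' 57 pre-exposure controls.
#'
#' @param nGenes number of genes in the displayed library.
#' @param peptidesPerGene tiled 49-aa peptides per gene.
#' @param peptideLen peptide length in residues (default 49, the T7
#'   display fragment length).
#' @param nPreControls,nComparators,nCases,nMockIP cohort sizes; `nMockIP`
#'   are bead-only mock-IP wells.
#' @param depthMean mean sequencing depth (reads/sample).
#' @param depthDispersion negative-binomial size parameter for depth (and
#'   count) overdispersion; larger = closer to Poisson.
#' @param backgroundConcentration Dirichlet concentration per peptide;
#'   values < 1 give the heavy-tailed background characteristic of phage
#'   display.
#' @param basalFraction mixture weight of the uniform basal-abundance
#'   component of the background (every clone is present in the library;
#'   the Dirichlet component models differential nonspecific stickiness on
#'   top of it).
#' @param sampleNoiseSD sdlog of the per-sample lognormal multiplicative
#'   noise on binding propensities.
#' @param plantedAntigens list of [plantedAntigen()] specifications; may be
#'   empty (null simulation).
#' @param phenotypeDefs named numeric vector, phenotype label -> fraction of
#'   cases flagged.
#' @param seed single integer; governs library, reactive-sample assignment
#'   and count draws, in that order.
#' @return A `SimulationConfig` object.
#' @examples
#' cfg <- simulationConfig(nGenes = 20, peptidesPerGene = 2,
#'                         nPreControls = 5, nComparators = 4, nCases = 6,
#'                         nMockIP = 2, depthMean = 1e4, seed = 7)
#' @export
simulationConfig <- function(nGenes = 200L, peptidesPerGene = 3L,
                             peptideLen = 49L, nPreControls = 57L,
                             nComparators = 64L, nCases = 121L,
                             nMockIP = 8L, depthMean = 1e5,
                             depthDispersion = 10, backgroundConcentration = 0.3,
                             basalFraction = 0.05,
                             sampleNoiseSD = 0.3, plantedAntigens = list(),
                             phenotypeDefs = numeric(), seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      peptidesPerGene = as.integer(peptidesPerGene),
      peptideLen = as.integer(peptideLen),
      nPreControls = as.integer(nPreControls),
      nComparators = as.integer(nComparators),
      nCases = as.integer(nCases), nMockIP = as.integer(nMockIP),
      depthMean = as.numeric(depthMean),
      depthDispersion = as.numeric(depthDispersion),
      backgroundConcentration = as.numeric(backgroundConcentration),
      basalFraction = as.numeric(basalFraction),
      sampleNoiseSD = as.numeric(sampleNoiseSD),
      plantedAntigens = plantedAntigens,
      phenotypeDefs = phenotypeDefs, seed = as.integer(seed))
}

#' @rdname simulationConfig
#' @export
setClass("SimulationConfig",
  representation(nGenes = "integer", peptidesPerGene = "integer",
                 peptideLen = "integer", nPreControls = "integer",
                 nComparators = "integer", nCases = "integer",
                 nMockIP = "integer", depthMean = "numeric",
                 depthDispersion = "numeric",
                 backgroundConcentration = "numeric",
                 basalFraction = "numeric",
                 sampleNoiseSD = "numeric", plantedAntigens = "list",
                 phenotypeDefs = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (sl in c("nGenes", "peptidesPerGene", "peptideLen", "nPreControls",
               "nComparators", "nCases", "nMockIP"))
    if (slot(object, sl) < 1L)
      msg <- c(msg, paste0(sl, " must be >= 1"))
  if (object@depthMean <= 0) msg <- c(msg, "depthMean must be > 0")
  if (object@backgroundConcentration <= 0)
    msg <- c(msg, "backgroundConcentration must be > 0")
  if (object@depthDispersion <= 0)
    msg <- c(msg, "depthDispersion must be > 0")
  if (object@basalFraction < 0 || object@basalFraction >= 1)
    msg <- c(msg, "basalFraction must be in [0, 1)")
  for (pa in object@plantedAntigens) {
    if (!all(c("gene_id", "target_cohorts", "prevalence",
               "effect_multiplier") %in% names(pa)))
      msg <- c(msg, "malformed planted antigen (use plantedAntigen())")
    else {
      if (pa$prevalence <= 0 || pa$prevalence > 1)
        msg <- c(msg, "prevalence must be in (0, 1]")
      if (pa$effect_multiplier <= 1)
        msg <- c(msg, "effect_multiplier must be > 1")
      if (!all(pa$target_cohorts %in% c("case", "comparator")))
        msg <- c(msg, "target_cohorts must be a subset of {case, comparator}")
    }
  }
  if (length(object@phenotypeDefs) &&
      (is.null(names(object@phenotypeDefs)) ||
       any(object@phenotypeDefs < 0 | object@phenotypeDefs > 1)))
    msg <- c(msg, "phenotypeDefs must be named fractions in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Specify one planted antigen reactivity
#'
#' @param geneId gene to make reactive (e.g. `"GENE0001"`; ids are assigned
#'   by [generateLibrary()] in order).
#' @param targetCohorts cohorts whose samples can be reactive; subset of
#'   `c("case", "comparator")`.
#' @param prevalence fraction of targeted samples that are reactive.
#' @param effectMultiplier multiplicative boost applied to the gene's peptide
#'   binding propensities in reactive samples, before renormalization (so the
#'   effect acts on binding, not directly on final counts).
#' @param restrictToPhenotype optional phenotype label; when set, only
#'   flagged case samples can be reactive.
#' @param focalPeptideOnly if `TRUE`, only the gene's first tiled peptide is
#'   boosted, emulating a single-fragment linear epitope.
#' @return A list consumed by [simulationConfig()].
#' @export
plantedAntigen <- function(geneId, targetCohorts = c("case", "comparator"),
                           prevalence, effectMultiplier,
                           restrictToPhenotype = NA_character_,
                           focalPeptideOnly = FALSE) {
  list(gene_id = geneId, target_cohorts = targetCohorts,
       prevalence = prevalence, effect_multiplier = effectMultiplier,
       restrict_to_phenotype = restrictToPhenotype,
       focal_peptide_only = isTRUE(focalPeptideOnly))
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.libStep <- 25L  # tiling step between consecutive peptides of a gene

.generateLibraryImpl <- function(config) {
  nPep <- config@nGenes * config@peptidesPerGene
  gw <- max(4L, nchar(as.character(config@nGenes)))
  genes <- sprintf(paste0("GENE%0", gw, "d"), seq_len(config@nGenes))
  geneOf <- rep(genes, each = config@peptidesPerGene)
  tile <- rep(seq_len(config@peptidesPerGene), times = config@nGenes)
  seqs <- vapply(seq_len(nPep), function(i)
    paste(sample(.AA20, config@peptideLen, replace = TRUE), collapse = ""),
    character(1))
  data.frame(
    peptide_id = sprintf("%s_p%02d", geneOf, tile),
    gene_id = geneOf,
    protein_name = geneOf,
    start_pos = (tile - 1L) * .libStep,
    aa_seq = seqs,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic tiled peptide library
#'
#' Produces `nGenes * peptidesPerGene` random amino-acid peptides of
#' `peptideLen` residues; consecutive peptides of a gene tile the (virtual)
#' protein with a 25-residue step, so start positions increase within a gene.
#' Deterministic for a fixed config seed.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with columns `peptide_id`, `gene_id`, `protein_name`,
#'   `start_pos`, `aa_seq`.
#' @export
generateLibrary <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(deriveSeed(config@seed, 1L), .generateLibraryImpl(config))
}

#' Simulate a PhIP-Seq cohort with planted reactivities
#'
#' Draws, per sample: a negative-binomial sequencing depth around
#' `depthMean`; peptide proportions from a shared Dirichlet background times
#' per-sample lognormal noise, with the planted antigens' peptides boosted by
#' `effectMultiplier` in reactive samples before renormalization; and finally
#' multinomial read counts. Mock-IP wells are drawn from the background law
#' only. Reactive samples are Bernoulli-assigned within the targeted cohorts
#' at the configured prevalence, and every assignment is recorded in the
#' ground-truth table (`groundTruth()` on the result).
#'
#' @param config a [simulationConfig()].
#' @param library optionally, the output of [generateLibrary()] on the same
#'   config (regenerated, and checked for consistency, when supplied).
#' @return A [PhIPSet-class]; `metadata()` carries `ground_truth`
#'   (antigen, sample_id, reactive) and `realized_prevalence`.
#' @examples
#' cfg <- simulationConfig(nGenes = 20, peptidesPerGene = 2,
#'                         nPreControls = 5, nComparators = 4, nCases = 6,
#'                         nMockIP = 2, depthMean = 1e4, seed = 7)
#' pset <- simulateCohort(cfg)
#' table(sampleRoles(pset))
#' @export
simulateCohort <- function(config, library = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  lib <- generateLibrary(config)
  if (!is.null(library)) {
    if (!identical(as.data.frame(library)$peptide_id, lib$peptide_id))
      stop("supplied library is inconsistent with config")
    lib <- as.data.frame(library)
  }
  libGenes <- unique(lib$gene_id)
  for (pa in config@plantedAntigens)
    if (!pa$gene_id %in% libGenes)
      stop("planted antigen gene not in library: ", pa$gene_id)

  roles <- c(rep("pre_control", config@nPreControls),
             rep("comparator", config@nComparators),
             rep("case", config@nCases),
             rep("mock_ip", config@nMockIP))
  ids <- c(sprintf("Pre%03d", seq_len(config@nPreControls)),
           sprintf("Conv%03d", seq_len(config@nComparators)),
           sprintf("Case%03d", seq_len(config@nCases)),
           sprintf("Mock%03d", seq_len(config@nMockIP)))
  nS <- length(ids)
  nPep <- nrow(lib)

  withSeed(deriveSeed(config@seed, 2L), {
    # shared background, one draw per library: a heavy-tailed Dirichlet
    # stickiness component mixed with a uniform basal component (every
    # clone is physically present in the library at comparable abundance)
    bg <- stats::rgamma(nPep, shape = config@backgroundConcentration, rate = 1)
    bg <- pmax(bg, 1e-12)
    bg <- (1 - config@basalFraction) * bg / sum(bg) +
      config@basalFraction / nPep

    # phenotype flags among cases
    pheno <- list()
    caseIdx <- which(roles == "case")
    for (lab in names(config@phenotypeDefs)) {
      fl <- logical(nS)
      fl[caseIdx] <- stats::runif(length(caseIdx)) < config@phenotypeDefs[[lab]]
      pheno[[paste0("pheno_", lab)]] <- fl
    }

    # reactive-sample assignment per planted antigen
    gt <- list()
    reactiveSets <- vector("list", length(config@plantedAntigens))
    for (k in seq_along(config@plantedAntigens)) {
      pa <- config@plantedAntigens[[k]]
      targ <- which(roles %in% pa$target_cohorts)
      if (!is.na(pa$restrict_to_phenotype)) {
        cn <- paste0("pheno_", pa$restrict_to_phenotype)
        if (is.null(pheno[[cn]]))
          stop("planted antigen restricted to unknown phenotype: ",
               pa$restrict_to_phenotype)
        targ <- intersect(targ, which(pheno[[cn]]))
      }
      reac <- targ[stats::runif(length(targ)) < pa$prevalence]
      reactiveSets[[k]] <- reac
      gt[[k]] <- data.frame(antigen = pa$gene_id, sample_id = ids[targ],
                            reactive = targ %in% reac,
                            stringsAsFactors = FALSE)
    }

    # count draws, one multinomial per sample
    counts <- matrix(0L, nPep, nS, dimnames = list(lib$peptide_id, ids))
    for (s in seq_len(nS)) {
      prop <- bg * stats::rlnorm(nPep, 0, config@sampleNoiseSD)
      for (k in seq_along(config@plantedAntigens)) {
        if (!(s %in% reactiveSets[[k]])) next
        pa <- config@plantedAntigens[[k]]
        idx <- which(lib$gene_id == pa$gene_id)
        if (pa$focal_peptide_only) idx <- idx[1L]
        prop[idx] <- prop[idx] * pa$effect_multiplier
      }
      prop <- prop / sum(prop)
      depth <- max(1L, stats::rnbinom(1, size = config@depthDispersion,
                                      mu = config@depthMean))
      counts[, s] <- stats::rmultinom(1, depth, prop)[, 1]
    }

    sheet <- data.frame(sample_id = ids, role = roles,
                        stringsAsFactors = FALSE)
    for (cn in names(pheno)) sheet[[cn]] <- pheno[[cn]]

    pset <- PhIPSet(counts, lib, sheet, phenotypes = names(pheno))
    gtAll <- if (length(gt)) do.call(rbind, gt)
             else data.frame(antigen = character(), sample_id = character(),
                             reactive = logical())
    metadata(pset)$ground_truth <- gtAll
    metadata(pset)$realized_prevalence <- if (length(gt))
      vapply(gt, function(d) mean(d$reactive), numeric(1))
    else numeric()
    metadata(pset)$config_seed <- config@seed
    pset
  })
}

#' Write simulated cohort inputs and ground truth to a directory
#'
#' @param pset a simulated [PhIPSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(pset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = writeCounts(phipCounts(pset), file.path(dir, "counts.tsv")),
    library = writePeptideLibrary(peptideLibrary(pset),
                                  file.path(dir, "library.tsv")),
    samplesheet = writeSampleSheet(sampleSheet(pset),
                                   file.path(dir, "samplesheet.tsv")))
  gt <- groundTruth(pset)
  if (!is.null(gt) && nrow(gt)) {
    p <- file.path(dir, "ground_truth.tsv")
    .writeTable(gt, p, "ground_truth")
    paths <- c(paths, ground_truth = p)
  }
  invisible(paths)
}
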