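suppressPackageStartupMessages({
  library(S4Vectors)
  library(SummarizedExperiment)
})

# Minimal hand-built PhIPSet for arithmetic checks: 3 peptides in 2 genes,
# 1 mock-IP + 3 pre-controls + 1 case.
tinyPhipSet <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(
      c(10, 2, 3, 4, 8,    # GA_p1
        5,  1, 2, 2, 4,    # GA_p2
        0,  0, 0, 0, 0),   # GB_p1  (zero gene)
      nrow = 3, byrow = TRUE,
      dimnames = list(c("GA_p1", "GA_p2", "GB_p1"),
                      c("mock1", "pre1", "pre2", "pre3", "case1")))
  }
  lib <- data.frame(
    peptide_id = c("GA_p1", "GA_p2", "GB_p1"),
    gene_id = c("GA", "GA", "GB"),
    protein_name = c("GA", "GA", "GB"),
    start_pos = c(0L, 25L, 0L),
    aa_seq = c("ACDEFGHIK", "LMNPQRSTV", "WYACDEFGH"))
  sheet <- data.frame(
    sample_id = colnames(counts),
    role = c("mock_ip", "pre_control", "pre_control", "pre_control", "case"))
  PhIPSet(counts, lib, sheet)
}

# Wrap an arbitrary fold-change matrix in a GeneSignalSet so z-scoring can
# be tested against hand-built values.
gssFromFC <- function(fc, roles) {
  stopifnot(ncol(fc) == length(roles))
  se <- SummarizedExperiment(
    assays = SimpleList(genes = fc, percent = fc, fc = fc),
    colData = DataFrame(role = roles, row.names = colnames(fc)))
  new("GeneSignalSet", se)
}

smallNullConfig <- function(seed, nGenes = 50, nCases = 15, nComparators = 15,
                            nPre = 8, nMock = 4) {
  simulationConfig(nGenes = nGenes, peptidesPerGene = 2,
                   nPreControls = nPre, nComparators = nComparators,
                   nCases = nCases, nMockIP = nMock, depthMean = 3e4,
                   seed = seed)
}
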