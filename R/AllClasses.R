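#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames rowData colData colData<-
#' @useDynLib phipkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.VALID_ROLES <- c("pre_control", "comparator", "case", "mock_ip")

#' PhIPSet: peptide-level PhIP-Seq experiment container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the raw
#' peptide x sample read-count matrix (assay `"counts"`), the peptide library
#' annotation as `rowData` (`gene_id`, `protein_name`, `start_pos`, `aa_seq`)
#' and the sample sheet as `colData` (`role` plus phenotype-flag and covariate
#' columns). Phenotype-flag column names are recorded in
#' `metadata(x)$phenotypes`. When produced by [simulateCohort()], the planted
#' ground truth is stored in `metadata(x)$ground_truth`.
#'
#' @section Validity:
#' Counts must be non-negative and non-missing; every `rowData` row needs a
#' `gene_id`, a non-negative `start_pos` and a sequence over the 20-letter
#' amino-acid alphabet (plus `X`); every sample's `role` must be one of
#' `pre_control`, `comparator`, `case`, `mock_ip`.
#'
#' @export
setClass("PhIPSet", contains = "SummarizedExperiment")

setValidity("PhIPSet", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (anyNA(cts)) msg <- c(msg, "counts contain missing values")
    else if (any(cts < 0)) msg <- c(msg, "counts contain negative values")
  }
  rd <- rowData(object)
  need <- c("gene_id", "start_pos", "aa_seq")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    if (any(rd$start_pos < 0)) msg <- c(msg, "start_pos must be >= 0")
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", rd$aa_seq)
    if (any(bad))
      msg <- c(msg, "aa_seq contains letters outside the amino-acid alphabet")
  }
  cd <- colData(object)
  if (!"role" %in% colnames(cd))
    msg <- c(msg, "colData lacks a 'role' column")
  else if (!all(cd$role %in% .VALID_ROLES))
    msg <- c(msg, paste0("unknown role token(s): ",
                         paste(unique(setdiff(cd$role, .VALID_ROLES)),
                               collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "peptide ids are not unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids are not unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PhIPSet from counts, library and sample sheet
#'
#' Cross-validates the three inputs: every count-matrix row must appear in the
#' peptide library, and every count-matrix column must have exactly one sample
#' sheet row. Rows of the result follow the count matrix.
#'
#' @param counts non-negative integer matrix, peptides x samples, with
#'   peptide ids as rownames and sample ids as colnames.
#' @param library `data.frame`/`DataFrame` with columns `peptide_id`,
#'   `gene_id`, `protein_name`, `start_pos` (0-based residue offset) and
#'   `aa_seq`.
#' @param samplesheet `data.frame`/`DataFrame` with columns `sample_id` and
#'   `role`; additional logical columns are phenotype flags when named in
#'   `phenotypes`, otherwise covariates.
#' @param phenotypes character vector naming the phenotype-flag columns of
#'   `samplesheet`.
#' @return A [PhIPSet-class] object.
#' @examples
#' cts <- matrix(0:3, 2, 2,
#'               dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' lib <- data.frame(peptide_id = c("p1", "p2"), gene_id = "G1",
#'                   protein_name = "G1", start_pos = c(0, 25),
#'                   aa_seq = c("ACDEFGHIKL", "MNPQRSTVWY"))
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     role = c("mock_ip", "pre_control"))
#' PhIPSet(cts, lib, sheet)
#' @export
PhIPSet <- function(counts, library, samplesheet, phenotypes = character()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have peptide rownames and sample colnames")
  library <- as.data.frame(library)
  samplesheet <- as.data.frame(samplesheet)
  # structural consistency only; the presence of mock-IP / reference samples
  # is a precondition of the enrichment ops, not of container construction
  validatePhipInputs(counts, library, samplesheet, requireRoles = character())
  rd <- library[match(rownames(counts), library$peptide_id), , drop = FALSE]
  rownames(rd) <- rd$peptide_id
  cd <- samplesheet[match(colnames(counts), samplesheet$sample_id), ,
                    drop = FALSE]
  rownames(cd) <- cd$sample_id
  stopifnot(all(phenotypes %in% colnames(cd)))
  se <- SummarizedExperiment(
    assays = SimpleList(counts = counts),
    rowData = DataFrame(rd[setdiff(colnames(rd), "peptide_id")]),
    colData = DataFrame(cd[setdiff(colnames(cd), "sample_id")]))
  out <- new("PhIPSet", se)
  metadata(out)$phenotypes <- phenotypes
  out
}

#' GeneSignalSet: gene-level derived PhIP-Seq signal
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass at gene resolution.
#' Assays are added stage by stage: `"genes"` (pseudocounted summed reads,
#' [collapseToGenes()]), `"percent"` (percent of total reads,
#' [percentNormalize()]), `"fc"` (fold change over mock IP,
#' [computeFoldChange()]), `"zscore"`/`"zdefined"` ([computeZScores()]) and
#' the logical call assays `"enriched"`/`"positive"` ([callReactivity()]).
#' Parameters (pseudocount, reference role, thresholds) are recorded in
#' `metadata()`.
#'
#' @export
setClass("GeneSignalSet", contains = "SummarizedExperiment")

setValidity("GeneSignalSet", function(object) {
  msg <- character()
  if (!"genes" %in% assayNames(object))
    msg <- c(msg, "assay 'genes' is required")
  if (!"role" %in% colnames(colData(object)))
    msg <- c(msg, "colData lacks a 'role' column")
  if (length(msg)) msg else TRUE
})

#' ClassifierResult: cross-validated L1 logistic regression output
#'
#' Holds, for one binary cohort contrast fit by [fitClassifier()]: per-gene
#' coefficients (averaged over fold models), per-fold held-out AUCs, the
#' pooled held-out AUC (the headline number), the pooled ROC curve, fold
#' assignments, held-out decision scores, labels, the inverse regularization
#' strength `C` and the seed.
#'
#' @slot contrast label of the contrast.
#' @slot coefficients named numeric, one per gene (mean across fold models).
#' @slot foldAUC numeric, held-out AUC per fold.
#' @slot pooledAUC numeric(1), AUC on pooled held-out scores.
#' @slot roc data.frame with columns `fpr`, `tpr`, `threshold`.
#' @slot folds named integer, fold assignment per sample.
#' @slot scores named numeric, pooled held-out decision scores.
#' @slot labels named logical, TRUE for the positive class.
#' @slot C numeric(1), inverse regularization strength.
#' @slot seed integer(1).
#' @export
setClass("ClassifierResult",
  representation(contrast = "character", coefficients = "numeric",
                 foldAUC = "numeric", pooledAUC = "numeric",
                 roc = "data.frame", folds = "integer", scores = "numeric",
                 labels = "logical", C = "numeric", seed = "integer"))

setValidity("ClassifierResult", function(object) {
  msg <- character()
  if (length(object@pooledAUC) != 1 || object@pooledAUC < 0 ||
      object@pooledAUC > 1)
    msg <- c(msg, "pooledAUC must be a single value in [0, 1]")
  if (length(object@folds) != length(object@labels))
    msg <- c(msg, "fold assignments must cover all samples")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhIPSet-class compact display
#' @param object a `PhIPSet`
#' @export
setMethod("show", "PhIPSet", function(object) {
  cat(sprintf("PhIPSet: %d peptides x %d samples (%d genes)\n",
              nrow(object), ncol(object),
              length(unique(rowData(object)$gene_id))))
  tb <- table(colData(object)$role)
  cat("  roles:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  ph <- metadata(object)$phenotypes
  if (length(ph)) cat("  phenotypes:", paste(ph, collapse = ", "), "\n")
  if (!is.null(metadata(object)$ground_truth))
    cat("  ground truth: ",
        nrow(metadata(object)$ground_truth), " planted entries\n", sep = "")
})

#' @describeIn GeneSignalSet-class compact display
#' @param object a `GeneSignalSet`
#' @export
setMethod("show", "GeneSignalSet", function(object) {
  cat(sprintf("GeneSignalSet: %d genes x %d samples\n",
              nrow(object), ncol(object)))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  md <- metadata(object)
  if (!is.null(md$reference_role))
    cat("  z-score reference:", md$reference_role, "\n")
  if (!is.null(md$threshold_fc))
    cat(sprintf("  calls: FC >= %g (enriched), z >= %g (positive)\n",
                md$threshold_fc, md$threshold_z))
})

#' @describeIn ClassifierResult-class compact display
#' @param object a `ClassifierResult`
#' @export
setMethod("show", "ClassifierResult", function(object) {
  cat(sprintf("ClassifierResult '%s': %d samples (%d positive), %d folds\n",
              object@contrast, length(object@labels), sum(object@labels),
              length(object@foldAUC)))
  cat(sprintf("  pooled AUC %.3f; per-fold AUC %s\n", object@pooledAUC,
              paste(sprintf("%.3f", object@foldAUC), collapse = ", ")))
})
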