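#' Accessors for PhIP-Seq containers
#'
#' `peptideLibrary()` returns the peptide annotation (`rowData` plus the
#' `peptide_id` column); `sampleSheet()` the sample metadata; `sampleRoles()`
#' the role vector named by sample; `groundTruth()` the planted-antigen truth
#' table of a simulated cohort (or `NULL`); `phipCounts()` the raw count
#' matrix.
#'
#' @param x a [PhIPSet-class] or [GeneSignalSet-class]
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peptideLibrary", function(x) standardGeneric("peptideLibrary"))

#' @rdname accessors
#' @export
setMethod("peptideLibrary", "PhIPSet", function(x) {
  rd <- as.data.frame(rowData(x))
  cbind(peptide_id = rownames(x), rd)
})

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

.sampleSheet <- function(x) {
  cd <- as.data.frame(colData(x))
  cbind(sample_id = colnames(x), cd)
}

#' @rdname accessors
#' @export
setMethod("sampleSheet", "PhIPSet", .sampleSheet)

#' @rdname accessors
#' @export
setMethod("sampleSheet", "GeneSignalSet", .sampleSheet)

#' @rdname accessors
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

.sampleRoles <- function(x) setNames(colData(x)$role, colnames(x))

#' @rdname accessors
#' @export
setMethod("sampleRoles", "PhIPSet", .sampleRoles)

#' @rdname accessors
#' @export
setMethod("sampleRoles", "GeneSignalSet", .sampleRoles)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("groundTruth", "PhIPSet", function(x) metadata(x)$ground_truth)

#' @rdname accessors
#' @export
setGeneric("phipCounts", function(x) standardGeneric("phipCounts"))

#' @rdname accessors
#' @export
setMethod("phipCounts", "PhIPSet", function(x) assay(x, "counts"))

.assayOrStop <- function(x, name, producer) {
  if (!name %in% assayNames(x))
    stop("assay '", name, "' not present; run ", producer, "() first",
         call. = FALSE)
  assay(x, name)
}

#' Derived-matrix accessors for GeneSignalSet
#'
#' Return the gene-level matrices of each normalization stage; each errors
#' with a pointer to the producing function when the stage has not been run.
#'
#' @param x a [GeneSignalSet-class]
#' @return A genes x samples matrix (logical for the call accessors).
#' @name signal-accessors
NULL

#' @rdname signal-accessors
#' @export
geneMatrix <- function(x) .assayOrStop(x, "genes", "collapseToGenes")

#' @rdname signal-accessors
#' @export
percentMatrix <- function(x) .assayOrStop(x, "percent", "percentNormalize")

#' @rdname signal-accessors
#' @export
fcMatrix <- function(x) .assayOrStop(x, "fc", "computeFoldChange")

#' @rdname signal-accessors
#' @export
zMatrix <- function(x) .assayOrStop(x, "zscore", "computeZScores")

#' @rdname signal-accessors
#' @export
zDefined <- function(x) .assayOrStop(x, "zdefined", "computeZScores")

#' @rdname signal-accessors
#' @export
enrichedCalls <- function(x) .assayOrStop(x, "enriched", "callReactivity")

#' @rdname signal-accessors
#' @export
positiveCalls <- function(x) .assayOrStop(x, "positive", "callReactivity")

#' ClassifierResult accessors
#'
#' @param x a [ClassifierResult-class]
#' @return `pooledAUC()`: the AUC on pooled held-out scores; `foldAUC()`: the
#'   per-fold held-out AUCs; `coefficients()`-style access via
#'   `classifierCoefficients()`; `rocPoints()`: data.frame of the pooled ROC
#'   curve.
#' @name classifier-accessors
NULL

#' @rdname classifier-accessors
#' @export
pooledAUC <- function(x) x@pooledAUC

#' @rdname classifier-accessors
#' @export
foldAUC <- function(x) x@foldAUC

#' @rdname classifier-accessors
#' @export
classifierCoefficients <- function(x) x@coefficients

#' @rdname classifier-accessors
#' @export
rocPoints <- function(x) x@roc
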