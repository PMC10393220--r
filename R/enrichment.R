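#' Collapse peptide counts to gene level with a pseudocount
#'
#' Sums reads over all peptides mapping to the same gene and adds 0.5 reads
#' to every gene, so genes with zero reads stay in all downstream arithmetic.
#' The pseudocount is applied once, at gene level after summation and before
#' percent normalization; mock-IP columns are pseudocounted identically,
#' which keeps every fold-change denominator strictly positive.
#'
#' @param x a [PhIPSet-class].
#' @param pseudocount reads added to each gene total (default 0.5).
#' @return A [GeneSignalSet-class] with assay `"genes"`.
#' @examples
#' cfg <- simulationConfig(nGenes = 10, peptidesPerGene = 2,
#'                         nPreControls = 4, nComparators = 3, nCases = 3,
#'                         nMockIP = 2, depthMean = 5e3, seed = 3)
#' gss <- collapseToGenes(simulateCohort(cfg))
#' @export
collapseToGenes <- function(x, pseudocount = 0.5) {
  stopifnot(is(x, "PhIPSet"))
  gid <- rowData(x)$gene_id
  g <- rowsum(assay(x, "counts") + 0, gid) + pseudocount
  g <- g[order(rownames(g)), , drop = FALSE]
  se <- SummarizedExperiment(assays = SimpleList(genes = g),
                             colData = colData(x))
  out <- new("GeneSignalSet", se)
  metadata(out)$pseudocount <- pseudocount
  metadata(out)$phenotypes <- metadata(x)$phenotypes
  out
}

#' Convert gene reads to percentage of total reads per sample
#'
#' Normalizes each sample (column) of the pseudocounted gene matrix to
#' percentages, removing sequencing-depth differences; every column of the
#' result sums to 100.
#'
#' @param gss a [GeneSignalSet-class] from [collapseToGenes()].
#' @return `gss` with assay `"percent"` added.
#' @export
percentNormalize <- function(gss) {
  stopifnot(is(gss, "GeneSignalSet"))
  g <- geneMatrix(gss)
  pct <- sweep(g, 2, colSums(g), "/") * 100
  assays(gss)$percent <- pct
  gss
}

#' Fold change over mock-IP background
#'
#' Divides each sample's gene read percentage by the mean percentage of the
#' same gene across the bead-only mock-IP wells, normalizing away nonspecific
#' background phage binding. Mock-IP columns themselves are carried through
#' for diagnostics.
#'
#' @param gss a [GeneSignalSet-class] with a `"percent"` assay.
#' @return `gss` with assay `"fc"` added.
#' @export
computeFoldChange <- function(gss) {
  stopifnot(is(gss, "GeneSignalSet"))
  pct <- percentMatrix(gss)
  mock <- which(colData(gss)$role == "mock_ip")
  if (length(mock) == 0)
    stop("fold change requires at least one mock_ip sample")
  denom <- rowMeans(pct[, mock, drop = FALSE])
  assays(gss)$fc <- pct / denom
  gss
}

#' Z-scores of fold change against a reference control cohort
#'
#' For each non-reference sample, the z-score of its fold change against the
#' mean and standard deviation of the reference cohort. Reference samples are
#' scored leave-one-out: each against the remaining reference samples only,
#' so a sample never inflates its own reference distribution. Genes whose
#' reference standard deviation is zero are flagged undefined (`zDefined()`),
#' never scored infinite. The standard deviation uses the sample (n-1)
#' convention by default.
#'
#' @param gss a [GeneSignalSet-class] with an `"fc"` assay.
#' @param referenceRole role of the reference cohort (default
#'   `"pre_control"`, the pre-exposure controls).
#' @param sdType `"sample"` (n-1 denominator) or `"population"` (n).
#' @return `gss` with assays `"zscore"` (NA where undefined) and `"zdefined"`
#'   added; `metadata()$reference_role` records the reference.
#' @export
computeZScores <- function(gss, referenceRole = "pre_control",
                           sdType = c("sample", "population")) {
  stopifnot(is(gss, "GeneSignalSet"))
  sdType <- match.arg(sdType)
  fc <- fcMatrix(gss)
  ref <- which(colData(gss)$role == referenceRole)
  n <- length(ref)
  if (n < 3)
    stop("z-scores require >= 3 '", referenceRole, "' reference samples")
  R <- fc[, ref, drop = FALSE]
  rs <- rowSums(R)
  rss <- rowSums(R * R)

  z <- matrix(NA_real_, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  zdef <- matrix(FALSE, nrow(fc), ncol(fc), dimnames = dimnames(fc))

  # full-reference moments, for non-reference samples
  m <- rs / n
  v <- (rss - n * m^2) / if (sdType == "sample") (n - 1) else n
  s <- sqrt(pmax(v, 0))
  ok <- s > 0
  nonref <- setdiff(seq_len(ncol(fc)), ref)
  for (j in nonref) {
    z[ok, j] <- (fc[ok, j] - m[ok]) / s[ok]
    zdef[ok, j] <- TRUE
  }

  # leave-one-out moments for each reference sample
  for (k in seq_len(n)) {
    j <- ref[k]
    ml <- (rs - R[, k]) / (n - 1)
    vl <- (rss - R[, k]^2 - (n - 1) * ml^2) /
      if (sdType == "sample") (n - 2) else (n - 1)
    sl <- sqrt(pmax(vl, 0))
    okl <- sl > 0
    z[okl, j] <- (fc[okl, j] - ml[okl]) / sl[okl]
    zdef[okl, j] <- TRUE
  }

  assays(gss)$zscore <- z
  assays(gss)$zdefined <- zdef
  metadata(gss)$reference_role <- referenceRole
  metadata(gss)$sd_type <- sdType
  gss
}

#' Call enrichment and positivity
#'
#' A (gene, sample) pair is *enriched* when its fold change over mock IP is
#' at least `thresholdFC` (boundary inclusive), and *positive* when its
#' z-score against the reference controls is at least `thresholdZ`. The two
#' calls are independent; pairs with undefined z-scores are never positive.
#' Thresholds are recorded in `metadata()`.
#'
#' @param gss a [GeneSignalSet-class] with `"fc"` and `"zscore"` assays.
#' @param thresholdFC fold-change threshold for enrichment (default 5).
#' @param thresholdZ z-score threshold for positivity (default 6).
#' @return `gss` with logical assays `"enriched"` and `"positive"` added.
#' @export
callReactivity <- function(gss, thresholdFC = 5, thresholdZ = 6) {
  stopifnot(is(gss, "GeneSignalSet"))
  fc <- fcMatrix(gss)
  z <- zMatrix(gss)
  zdef <- zDefined(gss)
  assays(gss)$enriched <- fc >= thresholdFC
  assays(gss)$positive <- zdef & !is.na(z) & z >= thresholdZ
  metadata(gss)$threshold_fc <- thresholdFC
  metadata(gss)$threshold_z <- thresholdZ
  gss
}

#' Run the full normalization chain
#'
#' Convenience wrapper: [collapseToGenes()], [percentNormalize()],
#' [computeFoldChange()], [computeZScores()], [callReactivity()].
#'
#' @inheritParams collapseToGenes
#' @inheritParams computeZScores
#' @inheritParams callReactivity
#' @return A fully populated [GeneSignalSet-class].
#' @export
normalizePhip <- function(x, pseudocount = 0.5,
                          referenceRole = "pre_control",
                          thresholdFC = 5, thresholdZ = 6) {
  gss <- collapseToGenes(x, pseudocount = pseudocount)
  gss <- percentNormalize(gss)
  gss <- computeFoldChange(gss)
  gss <- computeZScores(gss, referenceRole = referenceRole)
  callReactivity(gss, thresholdFC = thresholdFC, thresholdZ = thresholdZ)
}

#' Peptide-level epitope localization profile
#'
#' For one gene and a set of samples, the mean reads-per-100,000 of each of
#' the gene's tiled peptides (raw peptide reads scaled to each sample's total
#' reads), ordered by start position. The *focality* — the fraction of the
#' gene's total mean signal carried by its top peptide — is reported
#' alongside; focality near 1 indicates a single shared linear epitope.
#'
#' @param x a [PhIPSet-class].
#' @param gene gene id to profile.
#' @param samples character vector of sample ids (nonempty).
#' @return data.frame with columns `peptide_id`, `start_pos`, `mean_rp100k`,
#'   with attributes `gene` and `focality`.
#' @export
peptideProfile <- function(x, gene, samples) {
  stopifnot(is(x, "PhIPSet"), length(samples) >= 1)
  if (!all(samples %in% colnames(x)))
    stop("unknown sample id(s): ",
         paste(setdiff(samples, colnames(x)), collapse = ", "))
  idx <- which(rowData(x)$gene_id == gene)
  if (length(idx) == 0) stop("unknown gene: ", gene)
  cts <- assay(x, "counts")
  tot <- colSums(cts)[samples]
  rp <- sweep(cts[idx, samples, drop = FALSE], 2, tot, "/") * 1e5
  prof <- data.frame(peptide_id = rownames(x)[idx],
                     start_pos = rowData(x)$start_pos[idx],
                     mean_rp100k = rowMeans(rp),
                     stringsAsFactors = FALSE)
  prof <- prof[order(prof$start_pos), , drop = FALSE]
  rownames(prof) <- NULL
  tots <- sum(prof$mean_rp100k)
  attr(prof, "gene") <- gene
  attr(prof, "focality") <- if (tots > 0) max(prof$mean_rp100k) / tots
                            else NA_real_
  prof
}

#' Fraction of a cohort positive for a gene
#'
#' Share of the cohort's samples called positive (z >= threshold) for the
#' given gene — e.g. the fraction of post-infection samples positive for one
#' autoantigen.
#'
#' @param gss a [GeneSignalSet-class] after [callReactivity()].
#' @param gene gene id.
#' @param cohort roles defining the cohort (default all post-infection
#'   samples: cases plus comparators).
#' @return a single fraction in `[0, 1]`.
#' @export
positivityFraction <- function(gss, gene,
                               cohort = c("case", "comparator")) {
  pos <- positiveCalls(gss)
  if (!gene %in% rownames(pos)) stop("unknown gene: ", gene)
  cols <- which(colData(gss)$role %in% cohort)
  if (length(cols) == 0) stop("empty cohort: ", paste(cohort, collapse = ","))
  mean(pos[gene, cols])
}
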