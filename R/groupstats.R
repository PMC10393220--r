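#' Two-sample Kolmogorov-Smirnov test
#'
#' Wraps [stats::ks.test()] with the direction convention used throughout the
#' package: `alternative = "greater"` tests whether `x` is stochastically
#' *greater* than `y` (its ECDF lies below), the "increased signal in the
#' disease cohort" direction, with D the maximum of `F_y(t) - F_x(t)`;
#' `"two_sided"` uses D = max |F_x - F_y|. P-values use the exact
#' small-sample computation where [stats::ks.test()] provides it and the
#' asymptotic Kolmogorov distribution otherwise (`exact` forces the choice).
#' Ties are handled by evaluating the ECDF difference at pooled points.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param alternative `"two_sided"` or `"greater"` (x stochastically greater
#'   than y).
#' @param exact passed to [stats::ks.test()]; `NULL` = automatic crossover.
#' @return one-row data.frame: `D`, `p_value`, `alternative`, `n1`, `n2`.
#' @examples
#' ksTwoSample(c(1, 2, 3), c(4, 5, 6))              # disjoint: D = 1
#' ksTwoSample(rnorm(20) + 1, rnorm(20), "greater")
#' @export
ksTwoSample <- function(x, y, alternative = c("two_sided", "greater"),
                        exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2)
    stop("Kolmogorov-Smirnov test requires n >= 2 in both samples")
  # R's ks.test 'less' alternative is "ECDF of x below that of y",
  # i.e. x stochastically greater -- verified against a brute-force ECDF
  # sweep in the test suite.
  alt <- if (alternative == "two_sided") "two.sided" else "less"
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = alt,
                                        exact = exact))
  data.frame(D = unname(kt$statistic), p_value = kt$p.value,
             alternative = alternative,
             n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
}

#' Select samples by role and phenotype
#'
#' @param gss a [GeneSignalSet-class] or [PhIPSet-class].
#' @param role optionally, roles to keep.
#' @param phenotype optionally, a phenotype label (colData column
#'   `pheno_<label>`); keeps flagged samples when `flagged = TRUE`, unflagged
#'   when `FALSE`.
#' @param flagged see `phenotype`.
#' @return character vector of sample ids.
#' @export
selectSamples <- function(gss, role = NULL, phenotype = NULL, flagged = TRUE) {
  cd <- colData(gss)
  keep <- rep(TRUE, ncol(gss))
  if (!is.null(role)) keep <- keep & cd$role %in% role
  if (!is.null(phenotype)) {
    cn <- paste0("pheno_", phenotype)
    if (!cn %in% colnames(cd)) stop("unknown phenotype label: ", phenotype)
    keep <- keep & (cd[[cn]] == flagged)
  }
  colnames(gss)[keep]
}

#' Per-gene Kolmogorov-Smirnov scan between two sample groups
#'
#' Runs [ksTwoSample()] on the fold-change values of every gene between two
#' disjoint sample groups (group A first, so `alternative = "greater"` tests
#' for signal increased in group A). No multiple-testing adjustment is
#' applied by default, matching raw-p heatmap presentation;
#' Benjamini-Hochberg adjusted p-values are available as an opt-in column.
#'
#' @param gss a [GeneSignalSet-class] with an `"fc"` assay.
#' @param groupA,groupB character vectors of sample ids; nonempty, disjoint.
#' @param alternative `"two_sided"` or `"greater"` (group A greater).
#' @param adjust if `TRUE`, add a BH-adjusted `p_adj` column.
#' @return data.frame, one row per gene: `gene_id`, `D`, `p_value`, `n1`,
#'   `n2`, `alternative` (and `p_adj`), in gene order; sort by `p_value` for
#'   a ranking.
#' @export
antigenScan <- function(gss, groupA, groupB,
                        alternative = c("two_sided", "greater"),
                        adjust = FALSE) {
  alternative <- match.arg(alternative)
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("both sample groups must be nonempty")
  if (length(intersect(groupA, groupB)))
    stop("sample groups overlap: ",
         paste(utils::head(intersect(groupA, groupB), 3), collapse = ", "))
  fc <- fcMatrix(gss)
  missA <- setdiff(groupA, colnames(fc))
  if (length(missA)) stop("unknown sample id(s): ",
                          paste(missA, collapse = ", "))
  missB <- setdiff(groupB, colnames(fc))
  if (length(missB)) stop("unknown sample id(s): ",
                          paste(missB, collapse = ", "))
  res <- do.call(rbind, lapply(rownames(fc), function(g)
    ksTwoSample(fc[g, groupA], fc[g, groupB], alternative)))
  out <- cbind(gene_id = rownames(fc), res, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Phenotype-stratified one-sided antigen scans
#'
#' For each phenotype label, compares fold changes of flagged case samples
#' against the comparator cohort with a one-sided ("greater in phenotype")
#' KS test — the phenotype-heatmap computation.
#'
#' @param gss a [GeneSignalSet-class] with an `"fc"` assay.
#' @param phenotypes phenotype labels; defaults to all labels recorded at
#'   simulation/ingest time.
#' @param comparatorRole role of the comparison cohort.
#' @param alternative KS alternative; one-sided by default.
#' @return named list of [antigenScan()] data.frames, plus a `p_matrix`
#'   attribute (genes x phenotypes) of raw p-values for heatmap plotting.
#' @export
phenotypeScan <- function(gss, phenotypes = metadata(gss)$phenotypes,
                          comparatorRole = "comparator",
                          alternative = "greater") {
  phenotypes <- sub("^pheno_", "", phenotypes)
  if (length(phenotypes) == 0) stop("no phenotype labels available")
  compare <- selectSamples(gss, role = comparatorRole)
  res <- list()
  for (lab in phenotypes) {
    grpA <- selectSamples(gss, role = "case", phenotype = lab)
    if (length(grpA) == 0) {
      warning("phenotype '", lab, "' has no flagged case samples; skipped")
      next
    }
    res[[lab]] <- antigenScan(gss, grpA, compare, alternative = alternative)
  }
  if (length(res))
    attr(res, "p_matrix") <- vapply(res, function(d) d$p_value,
                                    numeric(nrow(res[[1]])))
  res
}

#' Tabulate presence of top-ranked antigens across cohorts
#'
#' For each gene of a ranked list (e.g. top-20 classifier coefficients or
#' top fold changes), records whether at least one sample of each cohort is
#' *enriched* (FC >= threshold) for it — the shared-antigen presence
#' tabulation underlying cross-cohort comparisons.
#'
#' @param gss a [GeneSignalSet-class] after [callReactivity()].
#' @param rankedGenes character vector of gene ids, best first.
#' @param k number of top genes to tabulate (truncated to the available
#'   genes).
#' @param rankSource tag recorded in the output (`"coefficient"` or `"fc"`).
#' @return data.frame with columns `gene_id`, `present_in_case`,
#'   `present_in_comparator`, `present_in_pre`, `rank_source`; attribute
#'   `summary` counts genes present in both post-infection cohorts and genes
#'   present in the pre-exposure controls.
#' @export
sharedAntigens <- function(gss, rankedGenes, k = 20,
                           rankSource = "coefficient") {
  if (k < 1) stop("k must be >= 1")
  rankedGenes <- rankedGenes[rankedGenes %in% rownames(gss)]
  genes <- utils::head(rankedGenes, k)
  enr <- enrichedCalls(gss)
  role <- colData(gss)$role
  presence <- function(g, r) any(enr[g, role == r])
  out <- data.frame(
    gene_id = genes,
    present_in_case = vapply(genes, presence, logical(1), r = "case"),
    present_in_comparator = vapply(genes, presence, logical(1),
                                   r = "comparator"),
    present_in_pre = vapply(genes, presence, logical(1), r = "pre_control"),
    rank_source = rankSource, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- c(
    n_in_both_post = sum(out$present_in_case & out$present_in_comparator),
    n_in_pre = sum(out$present_in_pre))
  out
}
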