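#' Cross-validated L1-regularized logistic regression on z-scores
#'
#' Discriminates two cohorts from gene-level z-scored fold changes with an
#' L1-penalized logistic regression (the lasso path solved by
#' [glmnet::glmnet()] at the single penalty corresponding to inverse
#' regularization strength `C`; `lambda = 1 / (n * C)`, matching the
#' liblinear-style objective `C * sum(logloss) + |w|_1`). Evaluation is
#' stratified k-fold cross-validation: each fold model is fit on (k-1)/k of
#' the samples and scored on the held-out fold. Per-fold AUCs and the AUC on
#' the pooled held-out scores are both reported; the pooled value is the
#' headline number. Undefined z entries (zero-variance reference genes) are
#' imputed to 0, neutral on the standardized scale. Features are not
#' re-standardized (z-scores already are).
#'
#' @param x a [GeneSignalSet-class] with a `"zscore"` assay, or a genes x
#'   samples numeric z-score matrix.
#' @param positive,negative sample ids of the two classes (positive = the
#'   class scored high, e.g. cases).
#' @param folds number of CV folds (default 5; 4/5 train, 1/5 test).
#' @param seed integer seed for the stratified fold assignment.
#' @param C inverse regularization strength (default 1.0).
#' @param contrast label stored in the result.
#' @return a [ClassifierResult-class].
#' @examples
#' z <- matrix(rnorm(50 * 40), 50, 40,
#'             dimnames = list(sprintf("G%02d", 1:50),
#'                             sprintf("S%02d", 1:40)))
#' z["G01", 1:20] <- z["G01", 1:20] + 10
#' res <- fitClassifier(z, positive = colnames(z)[1:20],
#'                      negative = colnames(z)[21:40], seed = 1)
#' pooledAUC(res)
#' topFeatures(res, 1)
#' @export
fitClassifier <- function(x, positive, negative, folds = 5, seed = 1,
                          C = 1.0, contrast = "contrast") {
  z <- if (is(x, "GeneSignalSet")) zMatrix(x) else as.matrix(x)
  samples <- c(positive, negative)
  miss <- setdiff(samples, colnames(z))
  if (length(miss)) stop("unknown sample id(s): ",
                         paste(miss, collapse = ", "))
  if (length(positive) == 0 || length(negative) == 0)
    stop("both classes must be present")
  if (folds < 2) stop("folds must be >= 2")
  if (folds > min(length(positive), length(negative)))
    stop("more folds than minority-class samples")
  if (length(intersect(positive, negative)))
    stop("classes overlap")

  X <- t(z[, samples, drop = FALSE])
  X[is.na(X)] <- 0
  y <- setNames(c(rep(TRUE, length(positive)), rep(FALSE, length(negative))),
                samples)

  # stratified, seeded fold assignment
  fold <- setNames(integer(length(samples)), samples)
  withSeed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })

  scores <- setNames(numeric(length(samples)), samples)
  foldAUC <- numeric(folds)
  coefMat <- matrix(0, ncol(X), folds,
                    dimnames = list(colnames(X), NULL))
  for (f in seq_len(folds)) {
    tr <- fold != f
    lambda <- 1 / (sum(tr) * C)
    # glmnet advises when a fold's class count is < 8; expected at these
    # cohort sizes and harmless for a fixed-lambda fit
    fit <- withCallingHandlers(
      glmnet::glmnet(X[tr, , drop = FALSE], factor(y[tr]),
                     family = "binomial", alpha = 1, lambda = lambda,
                     standardize = FALSE),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    coefMat[, f] <- as.numeric(fit$beta)
    sc <- as.numeric(stats::predict(fit, X[!tr, , drop = FALSE],
                                    type = "link"))
    scores[!tr] <- sc
    foldAUC[f] <- rankAUC(sc, y[!tr])
  }

  roc <- pROC::roc(response = y, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
  pooled <- as.numeric(pROC::auc(roc))
  pts <- pROC::coords(roc, "all", ret = c("threshold", "specificity",
                                          "sensitivity"), transpose = FALSE)
  rocdf <- data.frame(fpr = 1 - pts$specificity, tpr = pts$sensitivity,
                      threshold = pts$threshold)

  # Class= named explicitly: the C slot would otherwise partial-match it
  new(Class = "ClassifierResult", contrast = contrast,
      coefficients = rowMeans(coefMat), foldAUC = foldAUC,
      pooledAUC = pooled, roc = rocdf, folds = fold, scores = scores,
      labels = y, C = C, seed = as.integer(seed))
}

#' Top-ranked antigens by coefficient magnitude
#'
#' Genes sorted by descending absolute (fold-averaged) coefficient, ties
#' broken lexicographically by gene id; the signed coefficient is retained in
#' the output.
#'
#' @param result a [ClassifierResult-class].
#' @param k number of genes to return (default 20; truncated to the gene
#'   count).
#' @return data.frame with columns `gene_id`, `coefficient`, `rank`.
#' @export
topFeatures <- function(result, k = 20) {
  stopifnot(is(result, "ClassifierResult"))
  if (k <= 0) stop("k must be positive")
  co <- result@coefficients
  ord <- order(-abs(co), names(co))
  n <- min(k, length(co))
  data.frame(gene_id = names(co)[ord][seq_len(n)],
             coefficient = unname(co[ord][seq_len(n)]),
             rank = seq_len(n), stringsAsFactors = FALSE)
}

#' Classifiers for a set of subgroup contrasts
#'
#' Fits one [fitClassifier()] per named subgroup definition (e.g. each long
#' COVID symptom phenotype, or women with long COVID, against the
#' convalescent comparators). Subgroups with an empty class are skipped with
#' a warning and recorded in the `skipped` attribute.
#'
#' @param x z-score source as in [fitClassifier()].
#' @param subgroups named list; each element a list with character vectors
#'   `positive` and `negative`.
#' @inheritParams fitClassifier
#' @return named list of [ClassifierResult-class]; attribute `skipped` names
#'   the subgroups skipped for emptiness.
#' @export
subgroupClassifications <- function(x, subgroups, folds = 5, seed = 1,
                                    C = 1.0) {
  stopifnot(is.list(subgroups), !is.null(names(subgroups)))
  res <- list()
  skipped <- character()
  for (lab in names(subgroups)) {
    sg <- subgroups[[lab]]
    if (length(sg$positive) == 0 || length(sg$negative) == 0) {
      warning("subgroup '", lab, "' has an empty class; skipped")
      skipped <- c(skipped, lab)
      next
    }
    res[[lab]] <- fitClassifier(x, sg$positive, sg$negative, folds = folds,
                                seed = seed, C = C, contrast = lab)
  }
  attr(res, "skipped") <- skipped
  res
}

#' Write classifier outputs as tabular text
#'
#' @param result a [ClassifierResult-class].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeClassifierResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- gsub("[^A-Za-z0-9_.-]", "_", result@contrast)
  co <- topFeatures(result, k = length(result@coefficients))
  p1 <- file.path(dir, paste0("coefficients_", tag, ".tsv"))
  .writeTable(co, p1, "classifier_coefficients",
              c(contrast = result@contrast))
  p2 <- file.path(dir, paste0("roc_", tag, ".tsv"))
  .writeTable(result@roc, p2, "classifier_roc", c(contrast = result@contrast))
  summ <- data.frame(contrast = result@contrast,
                     n_pos = sum(result@labels),
                     n_neg = sum(!result@labels),
                     pooled_auc = result@pooledAUC,
                     mean_fold_auc = mean(result@foldAUC),
                     C = result@C, seed = result@seed)
  p3 <- file.path(dir, paste0("summary_", tag, ".tsv"))
  .writeTable(summ, p3, "classifier_summary")
  invisible(c(coefficients = p1, roc = p2, summary = p3))
}
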