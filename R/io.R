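#' Tabular and sequence I/O for the PhIP-Seq pipeline
#'
#' All tabular files are plain text with a header row; the delimiter is
#' auto-detected from the extension (`.csv` = comma, anything else = tab).
#' Writers prepend a `#`-prefixed comment line recording the tool version and
#' the writing function; readers skip `#` lines. Writers and readers are
#' mutually inverse on valid inputs.
#'
#' @param path file path.
#' @name phip-io
NULL

.delimFor <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.writeStamp <- function(con, what, params = character()) {
  extra <- if (length(params))
    paste0(" ", paste(names(params), params, sep = "=", collapse = " "))
  else ""
  writeLines(sprintf("# phipkit %s %s%s", .pkgVersion(), what, extra), con)
}

.writeTable <- function(df, path, what, params = character()) {
  sep <- .delimFor(path)
  con <- file(path, "w")
  on.exit(close(con))
  .writeStamp(con, what, params)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

.readTable <- function(path, colClasses = NA) {
  utils::read.table(path, sep = .delimFor(path), header = TRUE,
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = colClasses,
                    quote = "")
}

#' @describeIn phip-io Read a peptide x sample read-count matrix. First column
#'   is the peptide id, remaining columns one per sample. Duplicate ids,
#'   negative values and non-integer values are format errors naming the
#'   offending row/column.
#' @return `readCounts()`: integer matrix with peptide rownames and sample
#'   colnames.
#' @export
readCounts <- function(path) {
  df <- .readTable(path)
  if (ncol(df) < 2) stop("count file needs an id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate peptide id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample id(s) in header")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(m, 2, function(v) all(grepl("^[0-9]+$", v))))
    stop("non-integer value in column '", colnames(m)[bad[1]], "'")
  }
  badCell <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(badCell))
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 ids[badCell[1, 1]], colnames(m)[badCell[1, 2]]))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @describeIn phip-io Write a count matrix.
#' @param counts integer matrix as returned by [readCounts()].
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(peptide_id = rownames(counts), counts,
                   check.names = FALSE)
  .writeTable(df, path, "counts")
}

.LIB_COLS <- c("peptide_id", "gene_id", "protein_name", "start_pos", "aa_seq")

#' @describeIn phip-io Read a peptide library annotation table with columns
#'   `peptide_id`, `gene_id`, `protein_name`, `start_pos` (0-based) and
#'   `aa_seq`. Letters outside the 20-letter alphabet (plus `X`) are mapped to
#'   `X` with a warning.
#' @export
readPeptideLibrary <- function(path) {
  df <- .readTable(path, colClasses = "character")
  miss <- setdiff(.LIB_COLS, colnames(df))
  if (length(miss))
    stop("library file lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[.LIB_COLS]
  df$start_pos <- as.integer(df$start_pos)
  if (anyDuplicated(df$peptide_id))
    stop("duplicate peptide id(s) in library")
  if (any(is.na(df$start_pos)) || any(df$start_pos < 0))
    stop("start_pos must be a non-negative integer (0-based offset)")
  df$aa_seq <- toupper(df$aa_seq)
  unknown <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", df$aa_seq)
  if (any(unknown)) {
    warning(sum(unknown), " sequence(s) contain unknown letters; mapped to X")
    df$aa_seq <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", df$aa_seq)
  }
  df
}

#' @describeIn phip-io Write a peptide library table.
#' @param library data.frame as returned by [readPeptideLibrary()].
#' @export
writePeptideLibrary <- function(library, path) {
  .writeTable(as.data.frame(library)[.LIB_COLS], path, "peptide_library")
}

#' @describeIn phip-io Read a sample sheet with columns `sample_id` and `role`
#'   (one of `pre_control`, `comparator`, `case`, `mock_ip`); columns named
#'   `pheno_*` are parsed as logical phenotype flags, all other columns as
#'   character covariates. Unknown role tokens are an error.
#' @export
readSampleSheet <- function(path) {
  df <- .readTable(path, colClasses = "character")
  need <- c("sample_id", "role")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id(s)")
  bad <- setdiff(unique(df$role), .VALID_ROLES)
  if (length(bad))
    stop("unknown role token(s): ", paste(bad, collapse = ", "))
  for (cn in grep("^pheno_", colnames(df), value = TRUE))
    df[[cn]] <- as.logical(df[[cn]])
  df
}

#' @describeIn phip-io Write a sample sheet.
#' @param samplesheet data.frame as returned by [readSampleSheet()].
#' @export
writeSampleSheet <- function(samplesheet, path) {
  .writeTable(as.data.frame(samplesheet), path, "sample_sheet")
}

#' @describeIn phip-io Read a protein FASTA into a named
#'   [Biostrings::AAStringSet]; wrapped lines are concatenated per record.
#'   Empty files or empty sequences are an error.
#' @export
readProteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("proteome FASTA contains no records")
  if (any(Biostrings::width(aa) == 0)) stop("proteome contains empty sequences")
  if (anyDuplicated(sub("\\s.*$", "", names(aa))))
    stop("duplicate protein ids in proteome")
  aa
}

#' @describeIn phip-io Write a proteome FASTA.
#' @param proteome a named `AAStringSet` or named character vector.
#' @export
writeProteome <- function(proteome, path) {
  if (!methods::is(proteome, "AAStringSet"))
    proteome <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(proteome, path)
  invisible(path)
}

#' @describeIn phip-io Read/write a derived numeric matrix (percent, fold
#'   change, z-score); scientific notation is accepted.
#' @export
readMatrixFile <- function(path) {
  df <- .readTable(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate row id(s)")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @describeIn phip-io Write a derived numeric matrix.
#' @param mat numeric matrix with row and column names.
#' @param what short tag recorded in the provenance comment line.
#' @param params named character vector recorded in the comment line.
#' @export
writeMatrixFile <- function(mat, path, what = "matrix",
                            params = character()) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  .writeTable(df, path, what, params)
}

#' Cross-validate counts, peptide library and sample sheet
#'
#' Checks the structural consistency the downstream stages assume: every
#' counts row present in the library (orphan peptides are an error), every
#' counts column present in the sample sheet (and vice versa), and the
#' presence of at least one `mock_ip` and one `pre_control` sample, which the
#' fold-change and z-score stages require.
#'
#' @inheritParams PhIPSet
#' @param requireRoles roles that must each appear at least once.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validatePhipInputs <- function(counts, library, samplesheet,
                               requireRoles = c("mock_ip", "pre_control")) {
  orphan <- setdiff(rownames(counts), library$peptide_id)
  if (length(orphan))
    stop("peptide(s) in counts absent from library: ",
         paste(utils::head(orphan, 5), collapse = ", "),
         if (length(orphan) > 5) ", ...")
  missSheet <- setdiff(colnames(counts), samplesheet$sample_id)
  if (length(missSheet))
    stop("sample(s) in counts absent from sample sheet: ",
         paste(missSheet, collapse = ", "))
  extraSheet <- setdiff(samplesheet$sample_id, colnames(counts))
  if (length(extraSheet))
    stop("sample sheet row(s) without a counts column: ",
         paste(extraSheet, collapse = ", "))
  bad <- setdiff(unique(samplesheet$role), .VALID_ROLES)
  if (length(bad))
    stop("unknown role token(s): ", paste(bad, collapse = ", "))
  for (r in requireRoles)
    if (!any(samplesheet$role == r))
      stop("sample sheet contains no '", r, "' sample, required downstream")
  invisible(TRUE)
}
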