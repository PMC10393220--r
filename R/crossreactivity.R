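.AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# Gonnet PAM250 amino-acid substitution scores (Gonnet, Cohen & Benner 1992),
# embedded verbatim; row/column order ARNDCQEGHILKMFPSTWYV.
.GONNET_VALUES <- c(
  2.4, -0.6, -0.3, -0.3, 0.5, -0.2, 0.0, 0.5, -0.8, -0.8, -1.2, -0.4, -0.7, -2.3, 0.3, 1.1, 0.6, -3.6, -2.2, 0.1,
  -0.6, 4.7, 0.3, -0.3, -2.2, 1.5, 0.4, -1.0, 0.6, -2.4, -2.2, 2.7, -1.7, -3.2, -0.9, -0.2, -0.2, -1.6, -1.8, -2.0,
  -0.3, 0.3, 3.8, 2.2, -1.8, 0.7, 0.9, 0.4, 1.2, -2.8, -3.0, 0.8, -2.2, -3.1, -0.9, 0.9, 0.5, -3.6, -1.4, -2.2,
  -0.3, -0.3, 2.2, 4.7, -3.2, 0.9, 2.7, 0.1, 0.4, -3.8, -4.0, 0.5, -3.0, -4.5, -0.7, 0.5, 0.0, -5.2, -2.8, -2.9,
  0.5, -2.2, -1.8, -3.2, 11.5, -2.4, -3.0, -2.0, -1.3, -1.1, -1.5, -2.8, -0.9, -0.8, -3.1, 0.1, -0.5, -1.0, -0.5, 0.0,
  -0.2, 1.5, 0.7, 0.9, -2.4, 2.7, 1.7, -1.0, 1.2, -1.9, -1.6, 1.5, -1.0, -2.6, -0.2, 0.2, 0.0, -2.7, -1.7, -1.5,
  0.0, 0.4, 0.9, 2.7, -3.0, 1.7, 3.6, -0.8, 0.4, -2.7, -2.8, 1.2, -2.0, -3.9, -0.5, 0.2, -0.1, -4.3, -2.7, -1.9,
  0.5, -1.0, 0.4, 0.1, -2.0, -1.0, -0.8, 6.6, -1.4, -4.5, -4.4, -1.1, -3.5, -5.2, -1.6, 0.4, -1.1, -4.0, -4.0, -3.3,
  -0.8, 0.6, 1.2, 0.4, -1.3, 1.2, 0.4, -1.4, 6.0, -2.2, -1.9, 0.6, -1.3, -0.1, -1.1, -0.2, -0.3, -0.8, 2.2, -2.0,
  -0.8, -2.4, -2.8, -3.8, -1.1, -1.9, -2.7, -4.5, -2.2, 4.0, 2.8, -2.1, 2.5, 1.0, -2.6, -1.8, -0.6, -1.8, -0.7, 3.1,
  -1.2, -2.2, -3.0, -4.0, -1.5, -1.6, -2.8, -4.4, -1.9, 2.8, 4.0, -2.1, 2.8, 2.0, -2.3, -2.1, -1.3, -0.7, 0.0, 1.8,
  -0.4, 2.7, 0.8, 0.5, -2.8, 1.5, 1.2, -1.1, 0.6, -2.1, -2.1, 3.2, -1.4, -3.3, -0.6, 0.1, 0.1, -3.5, -2.1, -1.7,
  -0.7, -1.7, -2.2, -3.0, -0.9, -1.0, -2.0, -3.5, -1.3, 2.5, 2.8, -1.4, 4.3, 1.6, -2.4, -1.4, -0.6, -1.0, -0.2, 1.6,
  -2.3, -3.2, -3.1, -4.5, -0.8, -2.6, -3.9, -5.2, -0.1, 1.0, 2.0, -3.3, 1.6, 7.0, -3.8, -2.8, -2.2, 3.6, 5.1, 0.1,
  0.3, -0.9, -0.9, -0.7, -3.1, -0.2, -0.5, -1.6, -1.1, -2.6, -2.3, -0.6, -2.4, -3.8, 7.6, 0.4, 0.1, -5.0, -3.1, -1.8,
  1.1, -0.2, 0.9, 0.5, 0.1, 0.2, 0.2, 0.4, -0.2, -1.8, -2.1, 0.1, -1.4, -2.8, 0.4, 2.2, 1.5, -3.3, -1.9, -1.0,
  0.6, -0.2, 0.5, 0.0, -0.5, 0.0, -0.1, -1.1, -0.3, -0.6, -1.3, 0.1, -0.6, -2.2, 0.1, 1.5, 2.5, -3.5, -1.9, 0.0,
  -3.6, -1.6, -3.6, -5.2, -1.0, -2.7, -4.3, -4.0, -0.8, -1.8, -0.7, -3.5, -1.0, 3.6, -5.0, -3.3, -3.5, 14.2, 4.1, -2.6,
  -2.2, -1.8, -1.4, -2.8, -0.5, -1.7, -2.7, -4.0, 2.2, -0.7, 0.0, -2.1, -0.2, 5.1, -3.1, -1.9, -1.9, 4.1, 7.8, -1.1,
  0.1, -2.0, -2.2, -2.9, 0.0, -1.5, -1.9, -3.3, -2.0, 3.1, 1.8, -1.7, 1.6, 0.1, -1.8, -1.0, 0.0, -2.6, -1.1, 3.4)

#' The Gonnet PAM250 substitution matrix
#'
#' The published Gonnet (1992) PAM250 amino-acid exchange score matrix, on
#' the scale used by the Clustal similarity-symbol convention: pair score
#' > 0.5 defines "strongly similar" (`:`), score in (0, 0.5] "weakly similar"
#' (`.`). Symmetric; the diagonal is not required to dominate its row.
#'
#' @return 20 x 20 symmetric numeric matrix with amino-acid dimnames
#'   (order `ARNDCQEGHILKMFPSTWYV`), `name` attribute `"GonnetPAM250"`.
#' @examples
#' gonnetPAM250()["I", "V"]   # > 0.5: a strongly-similar pair
#' @export
gonnetPAM250 <- function() {
  m <- matrix(.GONNET_VALUES, 20, 20, byrow = TRUE,
              dimnames = list(.AA_ORDER, .AA_ORDER))
  attr(m, "name") <- "GonnetPAM250"
  m
}

# The standard 10 physicochemical amino-acid property classes
# (Livingstone & Barton / Zvelebil; the table behind the 0-11 conservation
# shading in common alignment viewers).
.AA_PROPS <- local({
  p <- list(
    hydrophobic = c("I","L","V","C","A","G","M","F","Y","W","H","K","T"),
    polar       = c("Y","W","H","K","R","E","Q","D","N","S","T","C"),
    small       = c("V","C","A","G","D","N","S","T","P"),
    proline     = c("P"),
    tiny        = c("A","G","S"),
    aliphatic   = c("I","L","V"),
    aromatic    = c("F","Y","W","H"),
    positive    = c("H","K","R"),
    negative    = c("D","E"),
    charged     = c("H","K","R","D","E"))
  m <- sapply(p, function(res) .AA_ORDER %in% res)
  rownames(m) <- .AA_ORDER
  t(m)  # 10 properties x 20 residues
})

#' The 10-property amino-acid classification table
#'
#' @return 10 x 20 logical matrix (properties x residues) used by
#'   [columnConservation()].
#' @export
aaPropertyTable <- function() .AA_PROPS

.checkResidues <- function(r, allowGap = TRUE, allowX = TRUE) {
  ok <- r %in% .AA_ORDER
  if (allowGap) ok <- ok | r == "-"
  if (allowX) ok <- ok | r == "X"
  if (!all(ok))
    stop("unknown residue(s): ", paste(unique(r[!ok]), collapse = ", "))
}

#' Clustal similarity symbol for a residue pair
#'
#' Per aligned column: `*` for identical residues; `:` when the Gonnet PAM250
#' score exceeds 0.5 (strongly similar); `.` when the score is in (0, 0.5]
#' (weakly similar); space otherwise. Gap columns, and columns involving `X`,
#' yield a space. Vectorized over equal-length residue vectors.
#'
#' @param a,b single residues or equal-length character vectors.
#' @param matrix substitution matrix (default [gonnetPAM250()]).
#' @return character vector of symbols.
#' @examples
#' pairSymbol("L", "L")  # "*"
#' pairSymbol("I", "V")  # ":"
#' @export
pairSymbol <- function(a, b, matrix = gonnetPAM250()) {
  a <- toupper(a); b <- toupper(b)
  stopifnot(length(a) == length(b))
  .checkResidues(a); .checkResidues(b)
  out <- rep(" ", length(a))
  std <- a %in% .AA_ORDER & b %in% .AA_ORDER
  out[std & a == b] <- "*"
  idx <- which(std & a != b)
  if (length(idx)) {
    sc <- matrix[cbind(a[idx], b[idx])]
    out[idx][sc > 0.5] <- ":"
    out[idx][sc > 0 & sc <= 0.5] <- "."
  }
  out
}

#' Physicochemical conservation score (0-11) for a residue pair
#'
#' 11 for identical residues; otherwise the number of the 10 standard
#' physicochemical properties (hydrophobic, polar, small, proline, tiny,
#' aliphatic, aromatic, positive, negative, charged) on which the two
#' residues agree — shared or jointly absent — so 10 means "all properties
#' conserved" despite differing residues. Gap columns and `X` score 0.
#' Vectorized.
#'
#' @inheritParams pairSymbol
#' @param properties property table (default [aaPropertyTable()]).
#' @return integer vector of scores in 0-11.
#' @examples
#' columnConservation("K", "K")  # 11
#' columnConservation("I", "L")  # 10: all properties conserved
#' @export
columnConservation <- function(a, b, properties = aaPropertyTable()) {
  a <- toupper(a); b <- toupper(b)
  stopifnot(length(a) == length(b))
  .checkResidues(a); .checkResidues(b)
  out <- integer(length(a))
  std <- a %in% .AA_ORDER & b %in% .AA_ORDER
  out[std & a == b] <- 11L
  idx <- which(std & a != b)
  if (length(idx))
    out[idx] <- as.integer(colSums(properties[, a[idx], drop = FALSE] ==
                                   properties[, b[idx], drop = FALSE]))
  out
}

# display string for conservation scores: '*' = 11, '+' = 10, digit otherwise
.conservationString <- function(scores) {
  ch <- as.character(scores)
  ch[scores == 11L] <- "*"
  ch[scores == 10L] <- "+"
  paste(ch, collapse = "")
}

.encodeAA <- function(s) {
  r <- strsplit(toupper(s), "")[[1]]
  .checkResidues(r, allowGap = FALSE, allowX = TRUE)
  match(r, .AA_ORDER)  # NA for X
}

# scoring helper tolerant of X (score 0)
.pairScores <- function(qi, ti, S) {
  sc <- numeric(length(qi))
  ok <- !is.na(qi) & !is.na(ti)
  sc[ok] <- S[cbind(qi[ok], ti[ok])]
  sc
}

#' Scan a peptide against a proteome for cross-reactive similarity
#'
#' Tests a molecular-mimicry hypothesis: slides (or locally aligns) a
#' candidate autoreactive peptide across every protein of a target proteome,
#' scoring with the Gonnet PAM250 matrix, and annotates each reported
#' alignment column with the Clustal similarity symbol and the 0-11
#' physicochemical conservation score.
#'
#' `mode = "ungapped"` scores every window `sum(S[q_i, t_(o+i)])` and ranks
#' all (protein, offset) windows. `mode = "local"` runs Smith-Waterman with
#' affine gaps (a gap of length L costs `gapOpening + L * gapExtension`) and
#' ranks the best local alignment per protein. Ties are broken by
#' (protein id, offset). Deterministic throughout.
#'
#' @param query amino-acid string, length >= 8 (typically a 49-residue
#'   displayed peptide).
#' @param proteome named `AAStringSet` or named character vector of target
#'   protein sequences.
#' @param matrix substitution matrix (default [gonnetPAM250()]).
#' @param mode `"ungapped"` sliding window or `"local"` Smith-Waterman.
#' @param topK number of hits to return.
#' @param gapOpening,gapExtension affine gap penalties for local mode
#'   (Clustal-style defaults 10 and 0.2 on the Gonnet scale).
#' @return data.frame of hits, best first: `protein_id`, `offset` (0-based
#'   target offset), `score`, `query_aln`, `target_aln` (gapped strings),
#'   `symbols`, `conservation` (display strings; `*`=11, `+`=10).
#' @examples
#' prot <- c(P1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
#' scanProteome("AKQRQISFVK", prot, mode = "ungapped", topK = 1)
#' @export
scanProteome <- function(query, proteome, matrix = gonnetPAM250(),
                         mode = c("ungapped", "local"), topK = 10,
                         gapOpening = 10, gapExtension = 0.2) {
  mode <- match.arg(mode)
  if (nchar(query) < 8) stop("query must be at least 8 residues")
  if (methods::is(proteome, "AAStringSet"))
    proteome <- setNames(as.character(proteome),
                         sub("\\s.*$", "", names(proteome)))
  if (length(proteome) == 0) stop("empty proteome")
  if (is.null(names(proteome)) || any(!nzchar(names(proteome))))
    stop("proteome sequences must be named")
  qi <- .encodeAA(query)
  qr <- strsplit(toupper(query), "")[[1]]
  L <- length(qi)
  S <- matrix

  hits <- list()
  for (pid in names(proteome)) {
    ti <- .encodeAA(proteome[[pid]])
    tr <- strsplit(toupper(proteome[[pid]]), "")[[1]]
    M <- length(ti)
    if (mode == "ungapped") {
      if (M < L) next
      nOff <- M - L + 1L
      sc <- numeric(nOff)
      for (i in seq_len(L))
        sc <- sc + .pairScores(rep(qi[i], nOff), ti[i:(i + nOff - 1L)], S)
      hits[[pid]] <- data.frame(protein_id = pid, offset = seq_len(nOff) - 1L,
                                score = sc, stringsAsFactors = FALSE)
    } else {
      S0 <- S
      qi0 <- qi; ti0 <- ti
      # X residues: score 0 against everything (extra alphabet row/col)
      S0 <- rbind(cbind(S0, 0), 0)
      qi0[is.na(qi0)] <- 21L
      ti0[is.na(ti0)] <- 21L
      al <- sw_align(qi0, ti0, S0, gapOpening, gapExtension)
      if (al$score <= 0) next
      qaln <- ifelse(al$q_idx == 0L, "-", qr[al$q_idx])
      taln <- ifelse(al$t_idx == 0L, "-", tr[al$t_idx])
      hits[[pid]] <- data.frame(protein_id = pid,
                                offset = al$t_start - 1L,
                                score = al$score,
                                query_aln = paste(qaln, collapse = ""),
                                target_aln = paste(taln, collapse = ""),
                                stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(protein_id = character(), offset = integer(),
                      score = numeric(), query_aln = character(),
                      target_aln = character(), symbols = character(),
                      conservation = character()))
  df <- do.call(rbind, hits)
  df <- df[order(-df$score, df$protein_id, df$offset), , drop = FALSE]
  df <- utils::head(df, topK)
  rownames(df) <- NULL

  if (mode == "ungapped") {
    df$query_aln <- paste(qr, collapse = "")
    df$target_aln <- vapply(seq_len(nrow(df)), function(i)
      substr(proteome[[df$protein_id[i]]], df$offset[i] + 1L,
             df$offset[i] + L), character(1))
  }
  ann <- lapply(seq_len(nrow(df)), function(i) {
    qa <- strsplit(df$query_aln[i], "")[[1]]
    ta <- strsplit(df$target_aln[i], "")[[1]]
    list(sym = paste(pairSymbol(qa, ta, S), collapse = ""),
         cons = .conservationString(columnConservation(qa, ta)))
  })
  df$symbols <- vapply(ann, `[[`, character(1), "sym")
  df$conservation <- vapply(ann, `[[`, character(1), "cons")
  df
}

#' Write a cross-reactivity hit table
#'
#' @param hits data.frame from [scanProteome()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeHitTable <- function(hits, path) {
  .writeTable(hits, path, "crossreactivity_hits")
}
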