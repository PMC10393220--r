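# Independent brute-force oracles, kept free of the code paths they check.

# KS D statistic by exhaustive ECDF-difference evaluation at every pooled
# point. alternative "greater" = x stochastically greater than y.
ksOracle <- function(x, y, alternative = "two_sided") {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  if (alternative == "two_sided") max(abs(Fx - Fy)) else max(Fy - Fx)
}

# Leave-one-out / full-reference z-scores recomputed from scratch with
# mean() and sd() per sample.
looZOracle <- function(fc, refCols) {
  z <- matrix(NA_real_, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  for (g in seq_len(nrow(fc))) {
    for (j in seq_len(ncol(fc))) {
      ref <- if (j %in% refCols) setdiff(refCols, j) else refCols
      m <- mean(fc[g, ref]); s <- sd(fc[g, ref])
      if (s > 0) z[g, j] <- (fc[g, j] - m) / s
    }
  }
  z
}

# Best local-alignment score by exhaustive enumeration of all monotone
# matchings between residue subsets (every gapped local alignment corresponds
# to one such matching; a gap of length L costs open + ext * L, terminal
# unaligned stretches are free). Feasible for sequence lengths <= 8.
swOracle <- function(q, t, S, open = 10, ext = 0.2) {
  qi <- match(strsplit(q, "")[[1]], rownames(S))
  ti <- match(strsplit(t, "")[[1]], colnames(S))
  n <- length(qi); m <- length(ti)
  gapcost <- function(L) ifelse(L == 0, 0, open + ext * L)
  best <- 0
  for (k in seq_len(min(n, m))) {
    qsets <- utils::combn(n, k)
    tsets <- utils::combn(m, k)
    for (a in seq_len(ncol(qsets))) {
      qs <- qsets[, a]
      qscore <- qi[qs]
      gq <- sum(gapcost(diff(qs) - 1))
      for (b in seq_len(ncol(tsets))) {
        ts <- tsets[, b]
        sc <- sum(S[cbind(qscore, ti[ts])]) - gq -
          sum(gapcost(diff(ts) - 1))
        if (sc > best) best <- sc
      }
    }
  }
  best
}

randomAA <- function(n, len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
}
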