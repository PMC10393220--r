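# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb the
# user's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a secondary 31-bit seed from a user seed, so that distinct stages
# (library generation vs. cohort draws) consume disjoint RNG streams while
# remaining a pure function of the one global seed.
deriveSeed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 1000003) %% 2147483647
}

.pkgVersion <- function() {
  as.character(utils::packageVersion("phipkit"))
}

# AUC by the rank (Mann-Whitney) formula; ties get midranks.
rankAUC <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
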