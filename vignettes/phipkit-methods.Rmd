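---
title: "phipkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phipkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phipkit)
```

# The analysis model

PhIP-Seq read counts confound three things: how deeply a sample was
sequenced, how sticky each phage clone is for the beads regardless of serum,
and the antibody reactivity one actually wants. The chain in `phipkit`
removes them in that order, at gene resolution.

**Gene collapse and pseudocount.** All peptide reads mapping to one gene are
summed and 0.5 reads are added per gene. The pseudocount is applied once, at
gene level after summation and before percent normalization; applying it per
peptide instead would scale with library design (a 3-peptide gene would
receive 1.5 reads) and change downstream fold changes, so the placement is
fixed and documented here. Mock-IP wells are pseudocounted identically,
which also guarantees a strictly positive fold-change denominator.

**Percent of total.** Each sample's gene vector is scaled to sum to 100.
This removes sequencing depth exactly: multiplying a sample's counts by any
constant leaves its percent column unchanged up to the (fixed) pseudocount,
a property the test suite checks both exactly (pseudocount 0) and at
realistic depth (relative tolerance 1e-3 at ~3×10⁴ reads).

**Fold change over mock IP.** Each gene percentage is divided by the mean
percentage of the same gene across the bead-only wells. This is the step
that assumes background stickiness is *shared* across samples: if each
sample had independent background, a bead-only average could not stand in
for it. The synthetic generator is built around the same assumption (below).
Mock wells are carried through the output for diagnostics; a sample whose
counts equal the single mock well has fold change exactly 1 everywhere.

**Z-scores and leave-one-out.** Fold changes are standardized against a
reference cohort (default `pre_control`, the pre-exposure sera). Reference
samples are scored against the *remaining* reference samples only;
otherwise each control would contribute to its own mean and standard
deviation and its z-scores would shrink toward zero, biasing any comparison
of controls with cases. The standard deviation uses the sample (n−1)
convention, configurable to population (n); at the reference sizes in
scope (tens of samples) the difference is a few percent of the z value, but
the choice must be fixed for reproducibility. At least 3 reference samples
are required so the leave-one-out standard deviation exists. Genes whose
reference standard deviation is zero are flagged undefined rather than
scored infinite — an invariant gene carries no evidence, and an infinite z
would otherwise convert a constant into the strongest call in the dataset.

**Calls.** *Enriched* means fold change ≥ 5; *positive* means z ≥ 6. Both
boundaries are inclusive, both thresholds are arguments recorded in the
output metadata, and the two calls are independent (a pair can be positive
without being enriched). Undefined z is never positive.

**Group comparisons.** Cohorts are compared per gene with two-sample
Kolmogorov–Smirnov tests on fold-change values. The one-sided alternative is
fixed as "first group stochastically greater" — the direction that asks for
signal *increased* in the disease group — and maps to
`stats::ks.test(..., alternative = "less")`, whose convention is about ECDF
dominance, not value dominance; the mapping is pinned by a brute-force ECDF
oracle in the tests. P-values use the exact small-sample computation where
`ks.test` provides it and the asymptotic Kolmogorov distribution otherwise
(`exact` argument exposed). No multiple-testing correction is applied by
default, matching the raw-p heatmap presentation common in this literature;
a Benjamini–Hochberg column is available by opting in (`adjust = TRUE`).
Ties are handled by evaluating ECDF differences at pooled points.

**Classification.** Cohort discrimination uses L1-penalized logistic
regression on the z-score matrix, the liblinear-style objective
`C·Σ logloss + |w|₁` solved by `glmnet` at the single penalty
`λ = 1/(n·C)`; the default inverse regularization strength is `C = 1`, the
common default where none is stated. Features are not re-standardized —
z-scores already are, and rescaling would silently change which antigens the
penalty keeps. Undefined z entries are imputed to 0, the neutral value on a
standardized scale. Evaluation is stratified, seeded k-fold cross-validation
(default 5; stratification avoids folds missing a class at these cohort
sizes). Both per-fold AUCs and the AUC of the pooled held-out scores are
reported; the pooled value is the headline because it uses every sample once
and is stable when folds are small. Reported coefficients are the mean
across the five fold models. Ranking ties at equal |coefficient| (mostly
exact zeros under L1) break lexicographically by gene id, so ranking is
deterministic.

**Epitope localization.** Peptide-level work uses raw reads scaled to reads
per 100,000 per sample, averaged over a sample set and ordered along the
protein. *Focality*, the fraction of a gene's mean signal on its top
peptide, summarizes whether reactivity concentrates on one linear fragment
(focality → 1) or spreads across the tiling (→ 1/k for k uniform peptides).

**Cross-reactivity.** The mimicry scan aligns a candidate self-peptide
against every protein of a target proteome under the Gonnet PAM250 matrix
(constants embedded from the published matrix; no external files). Two
modes: an ungapped sliding window ranking every (protein, offset), and
Smith–Waterman local alignment with affine gaps (a gap of length L costs
`open + L·extend`; Clustal-style defaults 10 and 0.2 on the Gonnet scale)
ranking the best alignment per protein. Adjacent insertion and deletion runs
are each charged a full opening, and ranking ties break by (protein id,
offset). The alignment is pairwise: scanning one peptide against one
proteome is a sequence of pairwise problems, so no profile/multiple
alignment machinery is involved. Each reported column carries the Clustal
symbol (`*` identity; `:` matrix score > 0.5; `.` in (0, 0.5]; space
otherwise, including gaps) and a 0–11 conservation score: 11 for identity,
otherwise the number of the ten standard physicochemical classes
(hydrophobic, polar, small, proline, tiny, aliphatic, aromatic, positive,
negative, charged) on which the pair agrees — shared *or jointly absent* —
so 10 (displayed `+`) means all properties conserved despite different
residues. Residues outside the 20-letter alphabet: `X` scores 0 against
everything and annotates as a blank; anything else is an alphabet error.

# The synthetic cohort generator

The generator exists to give the chain data whose truth is known. It
emulates exactly the structure the analysis assumes, no more:

- **Shared background.** One Dirichlet draw per library assigns each peptide
  a background binding propensity shared by *all* samples, mock wells
  included — the correlation that makes mock-IP normalization meaningful.
  The Dirichlet concentration (default 0.3 per peptide) makes the
  background heavy-tailed, as nonspecific phage binding is. A uniform
  basal component (default `basalFraction = 0.05`) is mixed in because
  every clone in a real library is physically present at roughly comparable
  abundance; without it the pure Dirichlet zero-tail produces clones with
  essentially no representation, and no finite antibody signal could ever
  be measured on them.
- **Per-sample noise.** Each sample multiplies the background by lognormal
  noise (`sampleNoiseSD`, default sdlog 0.3), giving fold changes a
  realistic spread around 1 in unreactive samples.
- **Depth.** Sequencing depth is negative-binomial around `depthMean`
  (default 10⁵ reads) with size `depthDispersion` (default 10); counts are
  one multinomial draw per sample. The defaults put the pseudocount two to
  three orders of magnitude below typical gene totals.
- **Planted reactivity.** Each planted antigen names a gene, the targeted
  cohorts, a prevalence, and a multiplicative boost applied to the gene's
  peptide propensities (or only its first tiled peptide, for the
  single-fragment pattern) in reactive samples *before* renormalization —
  the effect acts on binding, not on final counts, so totals stay
  realistic. Reactive samples are Bernoulli draws at the configured
  prevalence, optionally restricted to a phenotype flag, and every
  assignment is recorded in the ground-truth table.
- **Cohort sizes.** Defaults follow the study design the package targets:
  121 cases, 64 convalescent comparators, 57 pre-exposure controls. The
  number of bead-only wells is not something published designs agree on; 8
  is used as a typical batch.
- **Seeding.** One seed governs library, reactive assignment and count
  draws, in that order, through derived substreams; identical configs give
  bit-identical cohorts, and the caller's RNG state is never touched.

Because the effect is multiplicative on a heavy-tailed propensity, "how
strong is strong" matters. The recovery checks calibrate it in two regimes:
a boost of ~8 is the scale at which every reactive sample clears the z ≥ 6
positivity threshold while reactive z-scores stay within an order of
magnitude of the threshold — the regime in which ranking antigens by raw
coefficient magnitude is meaningful; boosts in the thousands drive most of a
reactive sample's reads to the planted peptide, the regime of a dominant
single-fragment epitope, used for the focality check. Problem sizes in the
acceptance runs (200–500 genes, 2–4 peptides/gene, cohorts of 10–121,
depth 10⁵, 10 seeds for the null properties) are the package's chosen
desk-scale study conditions.

What the generator does **not** emulate: phage amplification bias, PCR
duplicates, sequencing error, nucleotide-level reads, batch effects between
runs, or antibody cross-reactivity between related peptides. Passing
recovery tests therefore shows the chain is correct and well-calibrated
under its own assumptions — not that those assumptions hold for any given
real dataset.

# Numerical and interface choices

- Coordinates are 0-based residue offsets everywhere (`start_pos`, scan
  `offset`).
- Leave-one-out moments are computed from sufficient statistics
  (sums and sums of squares), with negative variances from cancellation
  clipped at zero; agreement with a from-scratch oracle is held to 1e-10
  relative error in the tests.
- Tabular files are tab-separated (comma for `.csv`), one `#` provenance
  comment line recording tool version; readers skip comments, accept
  scientific notation, and reject duplicate ids, negative counts and
  unknown role tokens with errors naming the offender. Unknown amino-acid
  letters are mapped to `X` with a warning on ingest.
- The pipeline validates its whole configuration before stage 1 (undefined
  phenotype labels, malformed contrasts, bad thresholds all fail fast),
  writes an MD5 manifest per artifact, aborts recording the failing stage,
  and on re-run with an unchanged config hash reuses the simulate/ingest
  outputs when their checksums are intact; later stages are deterministic,
  so reruns reproduce identical checksums.
- `fitClassifier` requires both classes non-empty and folds ≤ the
  minority-class size; subgroup runs skip empty subgroups with a warning
  rather than aborting a whole panel of contrasts.

# Limitations

- Gene-level z-scoring assumes the reference cohort is reactivity-free for
  most genes; a reference contaminated with true reactivities inflates
  σ_ref and masks calls.
- The L1 classifier reports sparse fold-averaged coefficients; when
  informative features are strongly correlated (overlapping reactive sets),
  the penalty keeps a subset per fold, and coefficient ranking across
  features of very different scales should be read with that in mind.
- KS p-values on fold changes treat genes independently; no correction is
  applied by default.
- The cross-reactivity scan scores physicochemical similarity only; it
  carries no alignment significance model (no E-values) and no structural
  or conformational epitope reasoning.
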