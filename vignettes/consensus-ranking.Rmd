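---
title: "Consensus ranking of polygenic score variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ranking of polygenic score variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsrank)
```

## The problem

Dozens of polygenic scores (PGS) are typically published for the same
complex trait, built with different methods (genome-wide significant
variants only, clumping-and-thresholding, Bayesian shrinkage models such as
LDpred2 or PRS-CS, LASSO-type penalized regression, and others) and from
different source GWAS. The scores disagree about which variants matter and
how much. `pgsrank` treats each scoring file as one ranked list of variants
— ranked by the absolute value of the per-allele effect weight — and asks
which variants are *consistently* highly ranked across scores. That is a
rank-aggregation problem, and the package implements six classical
algorithms for it, together with the curation steps needed before
aggregation is meaningful and an external benchmark to compare the
algorithms.

## Curation model

Aggregating redundant or unvalidated scores biases the consensus, so
curation runs first, in a fixed order:

1. **Identifier QC.** Only variants labelled `rs<digits>` are kept.
   Composite haplotype labels (e.g. the APOE ε2/ε3/ε4 labels, which denote
   combinations of rs429358 and rs7412) and coordinate-style identifiers
   cannot be placed in a single-SNP weighting framework and are dropped,
   each drop being recorded.
2. **Method classification.** A case-insensitive keyword table assigns each
   score to one of five categories (GWAS-SV, C+T, Bayesian, LASSO, Others).
   The table is ordered — Bayesian keywords are tried before C+T ones, so
   "LDpred2 after pruning" classifies as Bayesian — and a user-supplied
   override table always wins, preserving manual authority over edge cases.
3. **Redundancy.** Two scores are redundant when they share a source GWAS
   accession *and* use the identical variant set *and* matching weights
   (maximum absolute difference ≤ `tol`, default 1e-9 — weights distributed
   through text files can pick up last-digit formatting noise, so exact
   equality would be brittle, while any scientifically meaningful weight
   difference is orders of magnitude larger). Groups are the transitive
   closure of this relation. One representative per group is retained: the
   member whose variant set overlaps the trait's GWAS association rsIDs
   most, with a lexicographic pgs_id tie-break for reproducibility. Files
   that are strict subsets of another file are *not* considered redundant;
   redundancy means identical content.
4. **Limited scope.** A score none of whose variants appears in the
   external association table has no independent validation; it is excluded
   from the aggregation-eligible set but kept in the flag table and the
   annotated output.

Curation is idempotent and order-invariant (the collection is processed in
sorted pgs_id order internally), and every exclusion carries exactly one
audit-log line.

## The rank matrix

Let Q be the number of eligible scores and N the size of the union of their
rsIDs. Within each score, variants are ranked by |effect weight|, rank 1
being the largest; ties get the average of the tied positions, which keeps
the ranking invariant to row order (the choice of tie rule is ours — the
field convention of fractional ranking). Every variant *missing* from a
score is assigned that score's worst possible rank, N, giving a complete
N × Q matrix. N is global (the union), not per-file, because the fill rule
needs one common worst rank; with per-file N the filled columns would not
be comparable.

Five of the six methods consume normalized ranks. The default
normalization is **fractional**, r′ = r/N ∈ (0, 1]; strict positivity keeps
the geometric mean finite and matches the support of the uniform
order-statistic null models. Literal **min-max** scaling,
r′ = (r − 1)/(N − 1) ∈ [0, 1] (defined as 0 when N = 1), is retained as an
option; with it, a best-ranked variant hits exactly 0 and the geometric
mean is defined to be 0 for any vector containing a 0. Results always
record which mode was used.

## The six aggregation methods

* **Dowdall (mean reciprocal rank).** MRR(v) = (1/Q) Σᵢ 1/rankᵢ(v) on the
  raw N-filled matrix; a missing variant contributes 1/N. Values lie in
  (0, 1]; 1 is attained exactly by a variant ranked first everywhere, and
  1/N is the floor. Higher is better; it is the only method here whose
  score increases with consensus, and its scores are almost surely unique,
  which gives fine-grained aggregated ranks.
* **Robust Rank Aggregation.** For sorted normalized ranks
  r(1) ≤ … ≤ r(Q), pₖ = P(U(k) ≤ r(k)) where U(k) is the k-th order
  statistic of Q iid Uniform(0,1) draws, i.e. the Beta(k, Q−k+1)
  distribution function evaluated at r(k). The score is ρ = minₖ pₖ, with a
  Bonferroni correction min(1, Q·ρ) for having scanned Q order statistics.
  Small values indicate ranks far better than random order would produce.
* **Stuart.** The joint probability q = P(U(k) ≤ r(k) for *all* k
  simultaneously), evaluated exactly by the classical alternating recursion
  over the sorted ranks. We carry the recursion in the form
  uₖ = Σₜ (−1)^(t+1) C(k,t) r₍Q−k+1₎ᵗ uₖ₋ₜ (u₀ = 1, answer u_Q), which is
  algebraically the factorial-scaled version of the textbook recursion and
  never forms a bare factorial, so it stays finite far beyond the Q ≈ 170
  where `factorial()` overflows. Tiny negative values from floating-point
  cancellation in the alternating sum are clamped to 0; a non-finite result
  raises an error rather than propagating.
* **Borda minimum / geometric mean / arithmetic mean.** The three classical
  summaries of the normalized rank vector. Minimum rewards a single strong
  appearance; the means reward consistency.

For every method the aggregated rank 1..N is obtained by sorting scores
(descending for Dowdall, ascending otherwise) with ties broken by
lexicographic rsID — arbitrary, but deterministic and documented, which is
what reruns need. No randomness enters this module.

## Gene annotation

Nearest-gene assignment is proximity-only and strand-agnostic: a variant
inside a gene's BED interval gets distance 0; otherwise the distance is the
base count to the nearer gene boundary (an immediately adjacent variant has
distance 1), and equidistant or co-containing genes are resolved to the
lexicographically smallest name. Positions are 1-based in the domain model;
BED's 0-based half-open intervals are converted at the boundary. The
per-chromosome interval index is built on IRanges; a brute-force linear
scan serves as the oracle in the tests. Proximity is a deliberate
simplification — intergenic variants may well act on a farther gene, and no
transcript structure or QTL evidence is consulted.

## GWAS priority score and the benchmark

The external yardstick for a variant is
(mean |ln OR| over its genome-wide significant associations) × (number of
those associations). Natural log is used for the odds-ratio transform (the
conventional log-odds scale) and genome-wide significance is operationalized
as p ≤ 5 × 10⁻⁸; both are package choices where the upstream definitions are
implicit. A variant with no qualifying association scores 0 — most variants
do, while a handful score highly, so the distribution is strongly
right-skewed.

Each aggregation method is benchmarked by taking its top-k variants
(k = 100 by default, mirroring a top-100 reading of consensus lists),
pairing the rank positions 1..k with the variants' priority scores, and
computing Pearson's correlation. A good method front-loads high-priority
variants, so its r is *negative*. Variants without association support stay
in the top-k vector with priority 0; removing them would flatter methods
that rank unvalidated variants highly. `compare_methods()` repeats this per
subset (e.g. per method category plus "All") and averages each method's r
into an R_mean; undefined cells (empty subset, zero variance) are excluded
from the mean rather than imputed. Whether one should correlate rank
positions or raw consensus scores, over top-k or all variants, is genuinely
open; rank positions over top-k is our choice because it is
scale-free across methods with incomparable score units.

## The synthetic generator

`simulate_score_files()` plants a known consensus: of M = 500 variants
(rs1..rsM laid out deterministically on four synthetic chromosomes, 10 kb
apart), 20 planted variants enter each of Q = 8 files with probability 0.9
and carry |weight| ~ |N(3.0, 0.5)| with random sign; background variants
enter with probability 0.3 — low enough that the missing-rank-N rule is
exercised heavily — and carry N(0, 0.3) weights. The separation between
weight distributions is large by design: the defaults define the reference
recovery condition, not a difficulty dial. `simulate_associations()` gives
planted variants 1 + Poisson(3) genome-wide significant associations with
|ln OR| ~ |N(0.5, 0.1)|, and background variants Poisson(0.05) weak
associations, reproducing the "few variants with strong, repeated support"
shape of real association data. `simulate_gene_model()` tiles the layout
with genes covering a configurable fraction (default 0.6) of variant
positions. Everything is driven by a single required seed per operation
and regenerates byte-identically.

What the generator does *not* emulate: linkage disequilibrium between
variants (scores are sampled independently per file), realistic allele
frequencies or effect-size spectra, overlapping GWAS cohorts, and
coordinate conventions of real chromosomes. Passing the recovery tests
therefore shows the aggregation machinery is correct and well-calibrated on
independent lists, not that any particular real dataset will separate as
cleanly.

## Numerical and degenerate-input choices

* Tie-averaged within-file ranks; final-rank ties broken by rsID.
* Stuart evaluated in the binomial-coefficient recursion (above); RRA via
  `pbeta`, which for integer parameters equals the closed-form binomial
  tail polynomial (asserted to 1e-12 in the tests).
* Pearson correlation is reported as `NA` below 3 pairs or at zero
  variance instead of erroring, so benchmark tables degrade gracefully.
* An empty score after identifier QC is allowed: it is vacuously
  limited-scope and leaves the aggregation set.
* Weight round-tripping uses `%.17g` so written scoring files reparse to
  bit-identical doubles.

## Problem sizes used in the tests

The suite exercises the machinery at deliberately modest scale — rank
matrices up to 500 × 8 in the planted-recovery runs (seeds 1–5), 1,000
random 50 × 10 matrices for the MRR bound, 100,000-draw Monte-Carlo
calibrations of the RRA and Stuart null models for Q ∈ {1, 2, 3, 5}, and
≤ 200-gene annotation instances checked against a linear scan. These sizes
give comfortable statistical resolution (3 standard errors at 10⁵ draws)
while keeping a full run in tens of seconds; the algorithms themselves are
O(NQ log N) and have no scale-specific code paths.

## Known limitations

Rank aggregation over scores cannot see LD structure, so a consensus list
may contain several proxies of one signal; no imputation of missing ranks
is attempted (missing is defined as worst); the priority score only sees
variants with odds-ratio effect sizes in the association table; and
proximity annotation misassigns some intergenic regulatory variants. These
are scope boundaries, not bugs: each would require external data the
package deliberately does not fetch.
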