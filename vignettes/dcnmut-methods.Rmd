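---
title: "Methods: mutation burden over the DCN core–periphery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation burden over the DCN core–periphery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind `dcnmut`, in the order the pipeline runs them.

## Network construction

Domain hits with e-value ≤ 0.01 (the `e_value_max` default) define,
per protein, the set of distinct domain accessions; each such set is
added to the domain co-occurrence network as a clique. Repeated
occurrences of a domain inside one protein create no self-loop. The
`support` edge attribute counts proteins, not hit pairs, and is kept
for export only: all downstream analysis treats the graph as
unweighted, because the core decomposition is a degree-based
construction. Analysis runs on the largest connected component
(ties broken by the component holding the lexicographically smallest
accession, so the choice is deterministic); isolated nodes —
domains seen only in single-domain proteins — are retained up to the
component step and drop out there.

## Core decomposition and randomized ensembles

`kcore_decompose()` implements the bucket (ascending-degree)
algorithm, which is exactly equivalent to iteratively deleting all
nodes of degree < k for k = 1, 2, …; the test suite checks this
equivalence against a naive repeated-pruning oracle and against
`igraph::coreness` on random graphs. Profiles are computed over
*nested cores* (coreness ≥ k): they match the nested-core reading of
per-core claims such as "the inner cores contain no significant
domains". The chi-square test instead uses *shells* (coreness = k),
because a goodness-of-fit test needs disjoint categories; nested
cores are not a partition.

The null model for per-core statistics randomizes **membership, not
topology**: for each k, `n_replicates` (default 100) node sets of the
empirical core size N_k are drawn uniformly without replacement from
the analyzed component's node set. Empirical p-values use the add-one
estimator (1 + #extreme) / (1 + R), which cannot return 0 and makes
the smallest attainable p with 100 replicates ≈ 0.0099 — the natural
scale for reporting "p < 0.01 over 100 randomizations". Extremity is
two-sided by default (|replicate − ensemble mean| ≥ |observed −
ensemble mean|); one-sided alternatives are exposed because the
direction of interest is often known.

## Coordinate conversion and mapping

All internal coordinates are 1-based inclusive (the MAF and PfamScan
convention); the single exception is BED export, which subtracts 1
from starts. Residues `a..b` of a protein occupy CDS nucleotides
`3(a−1)+1 .. 3b` numbered in translation order — ascending genomic
position on the + strand, descending on −. The covering genomic
intervals are emitted in ascending order and merged when contiguous.
A domain reaching past the CDS, or a hit without a gene model, is an
error rather than a silent truncation. PfamScan *alignment*
coordinates (not envelope) are taken as the domain interval — the
conservative choice when only "peptide coordinates" is specified.

Mutation assignment is interval membership with inclusive bounds. A
mutation inside footprints of two different domains increments both
domains but counts once toward the mapped total; the per-domain
table and the mapped percentage are deliberately different
granularities. Overlap lookup goes through
`GenomicRanges::findOverlaps`; its results are checked in tests
against a linear membership scan.

## Scoring and significance

With m_d mapped mutations and L_d the cumulative genomic footprint
(bp over all occurrences), the normalized score is s_d = m_d / L_d.
Relative frequencies p_d = s_d / Σ s_d form a probability simplex
over domains — the only reading under which they can serve as a
Bernoulli success probability summing to one — and

z_d = p_d / √(p_d (1 − p_d)) = √(p_d / (1 − p_d)),

a strictly increasing transform of s_d, so the pre-lfdr significance
ranking is exactly the normalized-rate ranking. Unmutated domains get
z = 0 (the 0/0 limit consistent with "z = 0 iff m = 0"). Measuring
L_d in residues instead of bp rescales every s_d by the same factor 3
and leaves p and z unchanged.

The local false discovery rate is estimated as in the classic
empirical-null construction: bin the z values (120 bins), fit the
marginal density f by Poisson regression of bin counts on a
degree-7 orthogonal polynomial basis, estimate the null
N(δ0, σ0) with proportion π0 by a quadratic fit of log f over the
central bins (between the 25% and 75% data quantiles), and set
lfdr(z) = min(1, π0 f0(z)/f(z)), interpolated between bin midpoints
and clipped to [0, 1]. Bin count, degree and a theoretical-null
option are configurable. Fewer than 200 finite values is an error —
the density fit is not trustworthy there and exact alternatives
should be used. The pipeline's z values are small and strictly
positive rather than standard normal; the empirical null absorbs
their location and scale. A `transform = "log"` dialect fits on
log z for strictly-positive statistics (z = 0 cases are assigned
lfdr 1); the default remains the identity scale, which feeds z to
the estimator unchanged, and the tests show it recovers planted
signal cleanly at the default study scale. Significance is strict:
lfdr < 0.1; calls are ordered by lfdr, then z descending, then
accession, so output is deterministic under ties.

## Per-core tests

The trend statistic across core orders is Spearman rank correlation
between k and the per-core quantity — robust to the nonlinear decay
the depletion model produces; its null distribution recomputes the
same correlation per randomized replicate. The chi-square test
compares per-shell observed assignments with expectations
proportional to per-shell footprint length, the null consistent with
the length normalization used elsewhere; this length-proportional
expected-count construction is an assumption of this package.
Shells with expected < 5 are pooled into the next-lower shell
(configurable), and fewer than two categories after pooling is an
error.

## The synthetic-data generator

The generator emulates the statistical structure the analysis
assumes, with defaults chosen once as the package's study scale:

* 1500 domain families, 4000 proteins, 1–4 domain hits per protein
  drawn from a Zipf popularity law with exponent 1.0. These values
  give a largest component of roughly 1100–1200 nodes and ~5700
  edges with a deep nested core — the scale-free, core-heavy shape
  real proteome DCNs show, at a size a laptop handles comfortably.
* Domain family lengths uniform on 40–200 aa; linkers of 5–30 aa
  keep peptide intervals disjoint. Gene models have 1–5 CDS blocks,
  strand uniform, total block length exactly 3× the protein length;
  genes are laid head-to-tail per chromosome so footprints of
  different genes never overlap.
* 5% of hits get an e-value in (0.01, 1] so the construction filter
  is exercised.
* Mutations are single-nucleotide substitutions at a baseline rate
  of 0.03 per coding bp (chosen to yield ~50,000 records at this
  scale), depleted multiplicatively as exp(−β·coreness) with
  β = 0.2; 25 planted hot domains mutate at 10× the *baseline*
  (independent of coreness, matching how a fixed elevated rate is
  defined); non-domain coding sequence mutates at baseline so the
  mapped percentage is meaningful. 25% of records are labeled
  Silent and 5% RNA, independently of position, mimicking the
  classes the filter removes.
* Conservation labels are Bernoulli with
  P(conserved | k) = clamp(0.2 + 0.08 k, 0, 1).

What the generator does **not** emulate: trinucleotide mutational
signatures, indels and copy number, transcript isoforms (one protein
per gene), overlapping genes, inter-patient heterogeneity beyond a
barcode column, and any correlation between domain popularity and
domain length. Passing tests therefore demonstrate that the pipeline
recovers structure *of the planted kind* — rate gradients over
coreness and rate outliers — not that real tumor data satisfies the
model.

## Determinism and problem sizes

Every stochastic step takes a seed; a single pipeline seed fans out
to per-stage seeds by fixed offsets, so stages are individually
reproducible and a full rerun is byte-identical (asserted in the
test suite). The test suite runs the generator at two scales: a
reduced study (350 domains / 900 proteins) for pipeline and
profile tests, and the default scale for the end-to-end recovery
checks; oracle-equivalence tests use 100 random graphs (n ≤ 50),
1000 random gene models and 10 random mutation fixtures, and the
lfdr calibration uses 20 replicates of 5000 statistics.

## Known limitations

* The empirical-null fit assumes the null bulk dominates the center
  of the z distribution; with a very high signal fraction (≫ 25%)
  central matching will misestimate π0.
* The chi-square expectation model attributes all per-shell rate
  variation to footprint length; biological covariates (expression,
  replication timing) that real data would need are out of scope.
* The randomization null keeps topology fixed and shuffles
  membership only; it answers "are these core members special", not
  "is this topology special".
* Peptide-to-genomic conversion assumes one transcript per protein
  and clean gene models; it refuses rather than repairs
  inconsistent input.
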