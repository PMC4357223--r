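# dcnmut

Somatic mutation burden across the core–periphery structure of protein
domain co-occurrence networks.

## The problem

Protein domains that appear together in the same proteins form a
**domain co-occurrence network (DCN)**: each domain family is a node,
and two domains are joined by an edge when at least one protein
contains both, so every multi-domain protein contributes a clique. The
DCN of a proteome is scale-free-like and has a pronounced
core–periphery organization, which **k-core decomposition** exposes:
the k-core is the maximal subgraph in which every node keeps at least
k neighbors, cores are nested, and a node's *coreness* is the largest
k at which it survives the iterative pruning of low-degree nodes.

`dcnmut` asks how tumor somatic mutations distribute over that
organization. It maps mutations (MAF-dialect tables) onto domain
footprints obtained by converting Pfam peptide coordinates to genomic
coordinates through gene models, scores each domain d by its
length-normalized mutation rate

    s_d = m_d / L_d

(m_d mapped mutations, L_d the cumulative genomic length of all
occurrences of d), converts the relative frequencies
p_d = s_d / Σ s_d into the Bernoulli signal-to-noise statistic

    z_d = p_d / sqrt(p_d (1 − p_d)),

and calls significantly mutated domains at a **local false discovery
rate** below 0.1, using an empirical null (central matching on a
Poisson-regression density fit). Per-core profiles — mean normalized
score, percent conserved, percent significant — are compared against
ensembles of 100 size-matched random node sets, giving ensemble
z-scores, add-one empirical p-values, a randomization trend test
across core orders, and a shell-wise chi-square goodness-of-fit test
of observed versus footprint-expected mutation counts.

A first-class synthetic-data module generates proteomes, gene models,
conservation labels and mutation sets with the statistical structure
the analysis assumes — heavy-tailed domain usage, multi-exon genes on
both strands, a baseline point-mutation rate with a planted
multiplicative depletion of mutation rate with coreness and planted
10× "hot" domains — so the full pipeline is testable without external
data.

The package is for computational biologists studying how network
position constrains somatic mutability, and for anyone needing a
tested reference implementation of length-normalized, lfdr-thresholded
domain mutation scoring over k-core structure.

## Worked example

```r
library(dcnmut)

study <- synthesize_study(sim_config(seed = 1))
study$dcn                       # largest component of the DCN
print(study$decomposition)
#> Nested k-core decomposition: 1157 nodes, k_max = 17

rec <- filter_mutations(study$mutations)      # drop Silent / RNA
#> filter_mutations: removed 13857 Silent and 2846 RNA of 55464 records
fp  <- domain_footprints(study$hits, study$models)
cnt <- map_mutations(rec, fp)
print(cnt)
#> Mutation-to-domain assignment: 19962 of 38761 mutations mapped (51.5%)
#> across 1185 mutated domains

ds  <- domain_stats(cnt, fp)                  # s, p, z, lfdr per domain
print(ds)
#> Domain mutation statistics: 1202 domains, 25 significant at lfdr < 0.1
#> Empirical-null lfdr fit (central-matching, identity scale): pi0 = 0.974,
#> null = N(0.02391, 0.009058)

sig <- call_significant(ds)
mean(study$truth$hot_domains %in% sig)        # recall of planted hot domains
#> [1] 1

ens  <- random_core_ensembles(study$dcn, study$decomposition,
                              n_replicates = 100, seed = 8)
prof <- profile_cores(study$decomposition, ens, ds,
                      conservation = study$conservation)
trend_test(prof, "mean_s")
#> Core-order trend: Spearman rho = -0.966 (decreasing), empirical p = 0.009901

chi_square_cores(study$decomposition, fp, cnt)
#> Shell-wise goodness of fit: X-squared = 35237.715, df = 16, p = 0
```

The numbers mean: the mean normalized mutation score falls almost
monotonically with core order and no random membership ensemble
reproduces that gradient (p ≈ 1/101); all 25 planted hot domains are
recovered at lfdr < 0.1 with an estimated null proportion near 1; and
per-shell observed counts deviate far from footprint-proportional
expectation, as planted.

The same analysis runs from the shell over on-disk artifacts:

```sh
Rscript inst/cli/dcnmut.R run-all --outdir run1 --seed 1
```

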