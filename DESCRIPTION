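Package: dcnmut
Title: Somatic Mutation Burden Across the Core-Periphery Structure of
    Domain Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds protein domain co-occurrence networks (DCNs) from
    Pfam-style domain annotations, computes their nested k-core
    decomposition with size-matched randomized null ensembles, converts
    domain peptide coordinates to genomic footprints through gene models,
    maps somatic mutations (MAF dialect) onto domains, scores each domain
    by its length-normalized mutation rate, calls significantly mutated
    domains with an empirical-null local false discovery rate, and
    profiles mutation burden, conservation and significance across core
    orders, including randomization trend tests and a shell-wise
    chi-square goodness-of-fit test. Ships a synthetic-data generator
    that emulates the statistical structure of the inputs (heavy-tailed
    domain usage, multi-exon gene models on both strands, a baseline
    point-mutation process with planted coreness-dependent depletion and
    hot domains) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
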