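# Independent brute-force oracles. These deliberately avoid the code
# paths they check.

# Coreness by exhaustive repeated pruning: for each k, delete nodes of
# degree < k until stable; a node's coreness is the largest k at which
# it survives.
naive_coreness <- function(g) {
  nodes <- igraph::V(g)$name
  cn <- stats::setNames(rep(0L, length(nodes)), nodes)
  k <- 1L
  repeat {
    h <- g
    repeat {
      low <- igraph::V(h)[igraph::degree(h) < k]
      if (length(low) == 0L) break
      h <- igraph::delete_vertices(h, low)
    }
    if (igraph::vcount(h) == 0L) break
    cn[igraph::V(h)$name] <- k
    k <- k + 1L
  }
  cn
}

# Per-base enumeration: genomic coordinate of each CDS nucleotide in
# translation order, then the sorted positions covered by a residue
# range.
enumerate_cds <- function(blocks, strand) {
  per_block <- lapply(seq_len(nrow(blocks)),
                      function(i) blocks$start[i]:blocks$end[i])
  if (strand == "+") {
    unlist(per_block)
  } else {
    unlist(lapply(rev(per_block), rev))
  }
}

oracle_residue_positions <- function(blocks, strand, pep_start, pep_end) {
  cds <- enumerate_cds(blocks, strand)
  sort(cds[(3 * (pep_start - 1) + 1):(3 * pep_end)])
}

# expand an interval data.frame (chrom,start,end) to per-base positions
expand_intervals <- function(iv) {
  unlist(lapply(seq_len(nrow(iv)), function(i) iv$start[i]:iv$end[i]))
}

# O(n*m) membership scan of mutations against footprint intervals
oracle_map <- function(records, footprints) {
  iv <- footprints$intervals
  doms <- names(footprints$cumulative_length)
  m <- stats::setNames(integer(length(doms)), doms)
  mapped <- 0L
  for (i in seq_len(nrow(records))) {
    inside <- iv$chrom == records$chrom[i] &
      iv$start <= records$position[i] & records$position[i] <= iv$end
    hit_doms <- unique(iv$domain_acc[inside])
    if (length(hit_doms)) {
      mapped <- mapped + 1L
      m[hit_doms] <- m[hit_doms] + 1L
    }
  }
  list(m = m, mapped = mapped)
}

# all-pairs shortest-path histogram by breadth-first search
oracle_distance_histogram <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  dists <- c()
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (is.na(d[u])) { d[u] <- d[v] + 1L; queue <- c(queue, u) }
      }
    }
    keep <- which(seq_len(n) > s & !is.na(d))
    dists <- c(dists, d[keep])
  }
  table(dists)
}
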