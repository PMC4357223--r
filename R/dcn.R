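#' Build a domain co-occurrence network
#'
#' Nodes are distinct domain accessions surviving the e-value filter;
#' two domains are joined by an (unweighted) edge when they co-occur in
#' at least one protein, so each multi-domain protein contributes a
#' clique. Repeated occurrences of the same domain within one protein
#' yield a node but never a self-loop. The `support` edge attribute
#' counts proteins (not hit pairs) in which the pair co-occurs; it is
#' retained for export only — all downstream analysis is unweighted.
#'
#' @param hits Domain hit table ([read_pfamscan()] columns).
#' @param e_value_max Retain hits with e-value `<=` this bound
#'   (default 0.01).
#' @return An undirected simple `igraph` graph with vertex attribute
#'   `name` (accession) and edge attribute `support`.
#' @export
build_dcn <- function(hits, e_value_max = 0.01) {
  if (nrow(hits) == 0L) stop2("build_dcn: empty hit table")
  validate_hits(hits)
  keep <- hits$e_value <= e_value_max
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) {
    warning("all hits filtered out at e-value <= ", e_value_max,
            "; returning empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  # distinct (protein, domain) pairs, sorted for order-independence
  pd <- unique(data.frame(protein_id = hits$protein_id,
                          domain_acc = hits$domain_acc))
  pd <- pd[order(pd$protein_id, pd$domain_acc), ]
  doms_by_prot <- split(pd$domain_acc, pd$protein_id)
  pairs <- lapply(doms_by_prot, function(d) {
    if (length(d) < 2L) return(NULL)
    t(utils::combn(d, 2L))
  })
  nodes <- sort(unique(pd$domain_acc))
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    return(g)
  }
  key <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
  support <- table(key)
  uk <- sort(names(support))
  ends <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  el <- data.frame(from = ends[, 1L], to = ends[, 2L],
                   support = as.integer(support[uk]))
  igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = nodes))
}

#' Largest connected component of a DCN
#'
#' Ties on component size are broken deterministically by the component
#' containing the lexicographically smallest accession.
#'
#' @param dcn An igraph DCN.
#' @return The induced subgraph on the largest component.
#' @export
largest_component <- function(dcn) {
  if (igraph::vcount(dcn) == 0L) stop2("largest_component: empty graph")
  comp <- igraph::components(dcn)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(ci) {
      min(igraph::V(dcn)$name[comp$membership == ci])
    }, "")
    best <- best[order(firsts)][1L]
  }
  igraph::induced_subgraph(dcn, which(comp$membership == best))
}

#' Descriptive network statistics of a DCN
#'
#' Degree distribution, per-node local clustering coefficient, mean
#' clustering per degree, and the shortest-path-length histogram
#' (finite pairwise distances, i.e. within components).
#'
#' @param dcn An igraph DCN.
#' @return A list of data.frames: `degree_distribution` (degree, count),
#'   `clustering` (node, degree, clustering), `clustering_by_degree`
#'   (degree, mean_clustering), `path_length_histogram` (distance,
#'   count of unordered node pairs).
#' @export
network_stats <- function(dcn) {
  deg <- igraph::degree(dcn)
  dd <- as.data.frame(table(degree = deg), stringsAsFactors = FALSE)
  dd$degree <- as.integer(dd$degree)
  names(dd)[2L] <- "count"
  cc <- igraph::transitivity(dcn, type = "localundirected", isolates = "zero")
  clust <- data.frame(node = igraph::V(dcn)$name, degree = as.integer(deg),
                      clustering = cc)
  cbd <- stats::aggregate(clustering ~ degree, clust, mean)
  names(cbd)[2L] <- "mean_clustering"
  d <- igraph::distances(dcn)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d) & d > 0]
  ph <- if (length(d)) {
    h <- as.data.frame(table(distance = d), stringsAsFactors = FALSE)
    h$distance <- as.integer(h$distance)
    names(h)[2L] <- "count"
    h
  } else data.frame(distance = integer(), count = integer())
  list(degree_distribution = dd, clustering = clust,
       clustering_by_degree = cbd, path_length_histogram = ph)
}
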