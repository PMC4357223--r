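#' Nested k-core decomposition
#'
#' Computes the coreness (core order) of every node: the largest k such
#' that the node survives iterative pruning of all nodes with fewer than
#' k neighbors among the remaining nodes. Implemented with the
#' linear-time bucket algorithm (process nodes in ascending current
#' degree; a removed node decrements its neighbors' degrees), which is
#' equivalent to exhaustive repeated pruning for every k.
#'
#' @param dcn An igraph graph (typically the largest DCN component).
#' @return An object of class `core_decomposition`: list with `coreness`
#'   (named integer vector), `k_max`, and `nodes`.
#' @seealso [core_members()], [random_core_ensembles()]
#' @export
kcore_decompose <- function(dcn) {
  n <- igraph::vcount(dcn)
  if (n == 0L) stop2("kcore_decompose: empty graph")
  nm <- igraph::V(dcn)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  adj <- igraph::as_adj_list(dcn, mode = "all")
  adj <- lapply(adj, as.integer)
  deg <- vapply(adj, length, 1L)
  coreness <- integer(n)
  alive <- rep(TRUE, n)
  # bucket queue keyed by current degree
  ord <- order(deg)
  pos <- integer(n); pos[ord] <- seq_len(n)
  bin_start <- integer(max(deg) + 2L)
  for (d in 0:max(deg)) bin_start[d + 1L] <- sum(deg < d) + 1L
  bin_start[max(deg) + 2L] <- n + 1L
  cur <- deg
  for (i in seq_len(n)) {
    v <- ord[i]
    coreness[v] <- cur[v]
    alive[v] <- FALSE
    for (u in adj[[v]]) {
      if (alive[u] && cur[u] > cur[v]) {
        # swap u to the front of its degree bin, then shrink the bin
        du <- cur[u]
        pu <- pos[u]
        pw <- bin_start[du + 1L]
        w <- ord[pw]
        if (u != w) {
          ord[pu] <- w; ord[pw] <- u
          pos[u] <- pw; pos[w] <- pu
        }
        bin_start[du + 1L] <- pw + 1L
        cur[u] <- du - 1L
      }
    }
  }
  names(coreness) <- nm
  structure(list(coreness = coreness, k_max = max(coreness), nodes = nm),
            class = "core_decomposition")
}

#' @export
print.core_decomposition <- function(x, ...) {
  cat("Nested k-core decomposition:", length(x$nodes), "nodes, k_max =",
      x$k_max, "\n")
  cat("core sizes (k = 0..k_max):",
      paste(vapply(0:x$k_max, function(k) sum(x$coreness >= k), 1L),
            collapse = " "), "\n")
  invisible(x)
}

#' Members of the nested k-core
#'
#' Nodes with coreness >= k (so `core_members(d, 0)` is every node and
#' cores are nested). Use `shell = TRUE` for the shell (coreness == k),
#' a partition of the nodes.
#'
#' @param decomposition A `core_decomposition`.
#' @param k Core order.
#' @param shell Return the shell instead of the nested core.
#' @return Character vector of node names.
#' @export
core_members <- function(decomposition, k, shell = FALSE) {
  cn <- decomposition$coreness
  if (shell) names(cn)[cn == k] else names(cn)[cn >= k]
}

#' Size-matched randomized core ensembles
#'
#' For each core order k = 1..k_max, draws `n_replicates` node sets of
#' size N_k (the empirical nested k-core size) uniformly without
#' replacement from the analyzed graph's full node set. These ensembles
#' supply the null mean, variance and empirical p-value for any per-core
#' statistic.
#'
#' @param dcn The analyzed igraph graph (sampling universe).
#' @param decomposition Its `core_decomposition`.
#' @param n_replicates Replicates per core order (default 100).
#' @param seed Integer seed; ensembles are reproducible under it.
#' @return An object of class `core_ensembles`: list with `ensembles`
#'   (per k: list of character-vector replicates), `n_replicates`, `seed`.
#' @export
random_core_ensembles <- function(dcn, decomposition, n_replicates = 100,
                                  seed = 1L) {
  nodes <- igraph::V(dcn)$name
  stopifnot(setequal(nodes, decomposition$nodes))
  set.seed(seed)
  ks <- seq_len(decomposition$k_max)
  ens <- lapply(ks, function(k) {
    nk <- sum(decomposition$coreness >= k)
    stopifnot(nk <= length(nodes))
    replicate(n_replicates, sample(nodes, nk, replace = FALSE),
              simplify = FALSE)
  })
  names(ens) <- as.character(ks)
  structure(list(ensembles = ens, n_replicates = n_replicates,
                 seed = seed, nodes = nodes),
            class = "core_ensembles")
}

core_stat <- function(values, members) {
  v <- values[members]
  if (is.logical(v)) 100 * mean(v) else mean(v)
}

#' Per-core profile of a node attribute against the randomized null
#'
#' For each core order k the empirical statistic over the nested k-core
#' (mean for numeric attributes, percentage TRUE for logical ones) is
#' compared with the same statistic over each size-matched random
#' replicate: ensemble mean, ensemble sd, z-score, and the add-one
#' empirical p-value (1 + number of replicates at least as extreme) /
#' (1 + n_replicates).
#'
#' @param decomposition A `core_decomposition`.
#' @param ensembles Matching `core_ensembles`.
#' @param attribute Named numeric or logical vector over nodes. Nodes
#'   missing from it receive `default` (with a message).
#' @param default Value for nodes absent from `attribute` (0 / FALSE).
#' @param alternative Extremity rule for the empirical p: "two.sided"
#'   (|replicate - ensemble mean| >= |empirical - ensemble mean|),
#'   "greater", or "less".
#' @return data.frame with one row per k: `k`, `N_k`, `statistic`,
#'   `ensemble_mean`, `ensemble_sd`, `z`, `p_empirical`.
#' @export
core_attribute_profile <- function(decomposition, ensembles, attribute,
                                   default = if (is.logical(attribute)) FALSE else 0,
                                   alternative = c("two.sided", "greater",
                                                   "less")) {
  alternative <- match.arg(alternative)
  nodes <- decomposition$nodes
  miss <- setdiff(nodes, names(attribute))
  if (length(miss)) {
    message(length(miss), " node(s) missing from attribute; using default ",
            default)
    add <- rep(default, length(miss))
    names(add) <- miss
    attribute <- c(attribute, add)
  }
  rows <- lapply(seq_len(decomposition$k_max), function(k) {
    members <- core_members(decomposition, k)
    if (length(members) == 0L) {
      warning("empty core at k = ", k, "; row omitted")
      return(NULL)
    }
    emp <- core_stat(attribute, members)
    reps <- vapply(ensembles$ensembles[[as.character(k)]],
                   function(m) core_stat(attribute, m), 0)
    mu <- mean(reps); sdev <- stats::sd(reps)
    z <- if (sdev > 0) (emp - mu) / sdev else 0
    extreme <- switch(alternative,
      two.sided = abs(reps - mu) >= abs(emp - mu),
      greater = reps >= emp,
      less = reps <= emp)
    p <- (1 + sum(extreme)) / (1 + length(reps))
    data.frame(k = k, N_k = length(members), statistic = emp,
               ensemble_mean = mu, ensemble_sd = sdev, z = z,
               p_empirical = p)
  })
  do.call(rbind, rows)
}
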