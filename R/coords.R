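#' Convert a domain's peptide coordinates to genomic intervals
#'
#' Residues `pep_start..pep_end` of the protein cover CDS nucleotides
#' `3*(pep_start-1)+1 .. 3*pep_end`, where CDS nucleotides are numbered
#' in translation order: ascending genomic position on the + strand,
#' descending on the - strand. The covering genomic intervals are
#' returned in ascending genomic order (1-based inclusive), merged when
#' adjacent.
#'
#' @param hit Single-row domain hit (needs `protein_id`, `pep_start`,
#'   `pep_end`).
#' @param model Single-row gene model for the same protein.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
peptide_to_genomic <- function(hit, model) {
  if (hit$protein_id != model$protein_id)
    stop2("peptide_to_genomic: hit protein ", hit$protein_id,
          " does not match gene model protein ", model$protein_id)
  blocks <- gene_model_blocks(model)
  cds_to_genomic(blocks, model$strand, model$chrom,
                 3L * (hit$pep_start - 1L) + 1L, 3L * hit$pep_end,
                 who = paste0(hit$protein_id, " residues ", hit$pep_start,
                              "-", hit$pep_end))
}

# Genomic intervals covering CDS nucleotides n1..n2 (translation order).
cds_to_genomic <- function(blocks, strand, chrom, n1, n2, who = "query") {
  lens <- blocks$end - blocks$start + 1L
  total <- sum(lens)
  if (n2 > total)
    stop2("domain extends past CDS: ", who, " needs CDS nt ", n2,
          " but total CDS length is ", total)
  if (n1 < 1L) stop2("CDS nt start < 1 for ", who)
  ord <- if (strand == "+") seq_len(nrow(blocks)) else rev(seq_len(nrow(blocks)))
  hi <- cumsum(lens[ord])
  lo <- hi - lens[ord] + 1L
  out <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    if (hi[i] < n1 || lo[i] > n2) next
    o1 <- max(n1, lo[i]); o2 <- min(n2, hi[i])
    b <- ord[i]
    if (strand == "+") {
      gs <- blocks$start[b] + (o1 - lo[i])
      ge <- blocks$start[b] + (o2 - lo[i])
    } else {
      gs <- blocks$end[b] - (o2 - lo[i])
      ge <- blocks$end[b] - (o1 - lo[i])
    }
    out[[i]] <- c(gs, ge)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  out <- out[order(out[, 1L]), , drop = FALSE]
  # merge adjacent/contiguous intervals
  keep_s <- out[1L, 1L]; keep_e <- out[1L, 2L]
  ss <- es <- integer()
  for (i in seq_len(nrow(out))[-1L]) {
    if (out[i, 1L] <= keep_e + 1L) {
      keep_e <- max(keep_e, out[i, 2L])
    } else {
      ss <- c(ss, keep_s); es <- c(es, keep_e)
      keep_s <- out[i, 1L]; keep_e <- out[i, 2L]
    }
  }
  ss <- c(ss, keep_s); es <- c(es, keep_e)
  data.frame(chrom = rep(chrom, length(ss)), start = ss, end = es)
}

#' Genomic footprints of every domain
#'
#' Applies the e-value filter, converts every surviving hit to genomic
#' intervals via its gene model, and accumulates per-domain cumulative
#' footprint lengths (base pairs summed over all occurrences).
#'
#' @param hits Domain hit table.
#' @param models Gene model table (one row per protein).
#' @param e_value_max E-value cutoff matching the network construction
#'   (default 0.01).
#' @return Object of class `domain_footprints`: list with `intervals`
#'   (data.frame domain_acc, protein_id, chrom, start, end) and
#'   `cumulative_length` (named integer vector, bp per domain).
#' @export
domain_footprints <- function(hits, models, e_value_max = 0.01) {
  validate_hits(hits)
  hits <- hits[hits$e_value <= e_value_max, , drop = FALSE]
  if (nrow(hits) == 0L) stop2("domain_footprints: no hits survive filter")
  mi <- match(hits$protein_id, models$protein_id)
  if (anyNA(mi))
    stop2("domain_footprints: no gene model for protein(s): ",
          paste(utils::head(unique(hits$protein_id[is.na(mi)]), 5L),
                collapse = ", "))
  pieces <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    iv <- peptide_to_genomic(hits[i, ], models[mi[i], ])
    iv$domain_acc <- hits$domain_acc[i]
    iv$protein_id <- hits$protein_id[i]
    pieces[[i]] <- iv
  }
  intervals <- do.call(rbind, pieces)
  intervals <- intervals[c("domain_acc", "protein_id", "chrom",
                           "start", "end")]
  len <- intervals$end - intervals$start + 1L
  cumlen <- tapply(len, intervals$domain_acc, sum)
  cumlen <- stats::setNames(as.integer(cumlen), names(cumlen))
  structure(list(intervals = intervals, cumulative_length = cumlen),
            class = "domain_footprints")
}

#' @export
print.domain_footprints <- function(x, ...) {
  cat("Domain footprints:", length(x$cumulative_length), "domains,",
      nrow(x$intervals), "intervals,",
      sum(as.numeric(x$cumulative_length)), "bp total\n")
  invisible(x)
}
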