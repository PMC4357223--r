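#' Remove silent and RNA mutations
#'
#' Records whose variant classification is "Silent" or "RNA"
#' (case-insensitive) are dropped; everything else is retained. Removal
#' counts are reported via `message()`.
#'
#' @param records Mutation table ([read_maf()] columns).
#' @return The filtered table.
#' @export
filter_mutations <- function(records) {
  cls <- tolower(records$variant_classification)
  drop <- cls %in% c("silent", "rna")
  message("filter_mutations: removed ", sum(cls == "silent"),
          " Silent and ", sum(cls == "rna"), " RNA of ",
          nrow(records), " records")
  records[!drop, , drop = FALSE]
}

#' Assign mutations to domain footprints
#'
#' A mutation is assigned to domain d when its (chrom, position) lies
#' inside any interval of any occurrence of d (inclusive bounds). A
#' mutation inside the footprints of two different domains increments
#' both domains' counts but contributes once to the mapped total; a
#' mutation inside two occurrences of the same domain counts once for
#' that domain.
#'
#' @param records Mutation table (already filtered; see
#'   [filter_mutations()]).
#' @param footprints A `domain_footprints` object.
#' @return Object of class `domain_mutation_counts`: list with `counts`
#'   (data.frame `domain_acc`, `m` — every footprint domain, zeros
#'   kept), `M` (total records), `mapped` (records inside any
#'   footprint), `mapped_percentage`.
#' @export
map_mutations <- function(records, footprints) {
  iv <- footprints$intervals
  doms <- names(footprints$cumulative_length)
  m <- stats::setNames(integer(length(doms)), doms)
  mapped <- 0L
  if (nrow(records) > 0L) {
    fp_gr <- GenomicRanges::GRanges(
      iv$chrom, IRanges::IRanges(iv$start, iv$end))
    mut_gr <- GenomicRanges::GRanges(
      records$chrom, IRanges::IRanges(records$position, records$position))
    ov <- GenomicRanges::findOverlaps(mut_gr, fp_gr)
    mut_i <- S4Vectors::queryHits(ov)
    dom_i <- iv$domain_acc[S4Vectors::subjectHits(ov)]
    pair <- unique(paste(mut_i, dom_i, sep = "\r"))
    if (length(pair)) {
      dom_hit <- sub("^[0-9]+\r", "", pair)
      tab <- table(dom_hit)
      m[names(tab)] <- as.integer(tab)
    }
    mapped <- length(unique(mut_i))
  }
  M <- nrow(records)
  structure(list(
    counts = data.frame(domain_acc = doms, m = as.integer(m)),
    M = M, mapped = mapped,
    mapped_percentage = if (M > 0L) 100 * mapped / M else NA_real_),
    class = "domain_mutation_counts")
}

#' @export
print.domain_mutation_counts <- function(x, ...) {
  cat("Mutation-to-domain assignment: ", x$mapped, " of ", x$M,
      " mutations mapped (", sprintf("%.1f", x$mapped_percentage),
      "%) across ", sum(x$counts$m > 0L), " mutated domains\n", sep = "")
  invisible(x)
}
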