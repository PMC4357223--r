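#' Read PfamScan domain hits
#'
#' Parses the whitespace-separated tabular output of `pfam_scan.pl`
#' (comment lines start with `#`). Alignment start/end columns are taken
#' as the domain's peptide coordinates; envelope coordinates are ignored.
#'
#' @param path Path to a PfamScan output file.
#' @return A data.frame with columns `protein_id`, `domain_acc`,
#'   `domain_name`, `pep_start`, `pep_end`, `e_value` (one row per hit).
#' @export
read_pfamscan <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    warning("no data rows in ", path)
    return(empty_hits())
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 13L))
    stop2("parse error in ", path, " line ", lineno[which(nf < 13L)[1L]],
          ": expected >= 13 whitespace-separated columns (through E-value)")
  get <- function(i) vapply(fields, `[`, "", i)
  pep_start <- suppressWarnings(as.integer(get(2L)))
  pep_end <- suppressWarnings(as.integer(get(3L)))
  e_value <- suppressWarnings(as.numeric(get(13L)))
  bad <- is.na(pep_start) | is.na(pep_end) | is.na(e_value)
  if (any(bad))
    stop2("parse error in ", path, " line ", lineno[which(bad)[1L]],
          ": non-numeric alignment coordinates or E-value")
  hits <- data.frame(protein_id = get(1L), domain_acc = get(6L),
                     domain_name = get(7L), pep_start = pep_start,
                     pep_end = pep_end, e_value = e_value)
  validate_hits(hits, path)
  hits
}

empty_hits <- function() {
  data.frame(protein_id = character(), domain_acc = character(),
             domain_name = character(), pep_start = integer(),
             pep_end = integer(), e_value = numeric())
}

validate_hits <- function(hits, where = "domain hits") {
  if (any(hits$pep_start < 1L | hits$pep_end < hits$pep_start))
    stop2(where, ": invalid peptide interval (need 1 <= start <= end)")
  if (any(hits$e_value < 0)) stop2(where, ": negative e-value")
  invisible(hits)
}

#' Read somatic mutations from a MAF-dialect table
#'
#' Tab-separated with a header. The minimal column subset is matched
#' case-insensitively: Chromosome, Start_position (Start_Position also
#' accepted), Reference_Allele, Tumor_Seq_Allele2,
#' Variant_Classification, Tumor_Sample_Barcode. Chromosome names are
#' normalized by stripping a leading "chr". No filtering happens here;
#' see [filter_mutations()].
#'
#' @param path Path to a MAF file.
#' @param cancer_type Optional label attached to every record.
#' @return A data.frame with columns `chrom`, `position`, `ref_allele`,
#'   `alt_allele`, `variant_classification`, `sample_id`, `cancer_type`.
#' @export
read_maf <- function(path, cancer_type = NA_character_) {
  if (!file.exists(path)) stop2("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, comment.char = "#")
  want <- c(chrom = "chromosome", position = "start_position",
            ref_allele = "reference_allele",
            alt_allele = "tumor_seq_allele2",
            variant_classification = "variant_classification",
            sample_id = "tumor_sample_barcode")
  lc <- tolower(names(tab))
  idx <- match(want, lc)
  if (anyNA(idx))
    stop2("MAF parse error in ", path, ": missing column(s): ",
          paste(want[is.na(idx)], collapse = ", "))
  out <- stats::setNames(tab[idx], names(want))
  if (nrow(out) == 0L) {
    out$position <- integer()
  } else {
    pos <- suppressWarnings(as.integer(out$position))
    if (anyNA(pos))
      stop2("MAF parse error in ", path, " data row ",
            which(is.na(pos))[1L], ": non-integer Start_position")
    out$position <- pos
  }
  out$chrom <- sub("^chr", "", out$chrom)
  out$cancer_type <- rep(cancer_type, nrow(out))
  validate_mutations(out, path)
  out
}

validate_mutations <- function(rec, where = "mutation table") {
  if (any(rec$position < 1L)) stop2(where, ": position < 1")
  if (any(rec$ref_allele == rec$alt_allele))
    stop2(where, ": ref allele equals alt allele")
  invisible(rec)
}

#' Read gene models
#'
#' TSV with header columns gene_id, protein_id, chrom, strand,
#' cds_blocks, where cds_blocks is `"start-end,start-end"` in ascending
#' genomic order (1-based inclusive). Validation is strict: unsorted or
#' overlapping blocks, or a total length not divisible by 3, are errors.
#'
#' @param path Path to a gene model TSV.
#' @return A data.frame with one row per gene model; `cds_blocks` is kept
#'   as the string encoding, use [gene_model_blocks()] for parsed blocks.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("gene_id", "protein_id", "chrom", "strand", "cds_blocks")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop2("gene model parse error in ", path, ": missing column(s): ",
          paste(miss, collapse = ", "))
  tab <- tab[need]
  if (any(!tab$strand %in% c("+", "-")))
    stop2("gene model parse error in ", path, ": strand must be + or -")
  for (i in seq_len(nrow(tab))) {
    check_blocks(parse_blocks(tab$cds_blocks[i]),
                 where = paste0("gene model ", tab$gene_id[i]))
  }
  if (anyDuplicated(tab$protein_id))
    stop2("gene model parse error in ", path,
          ": duplicated protein_id (one transcript per protein expected)")
  tab
}

#' Parsed CDS blocks of one gene model row
#'
#' @param model A single-row gene model data.frame.
#' @return data.frame with columns `start`, `end` (ascending genomic order).
#' @export
gene_model_blocks <- function(model) {
  parse_blocks(model$cds_blocks[[1L]])
}

#' Read per-domain conservation labels
#'
#' TSV with header columns domain_acc, conserved (TRUE/FALSE or 1/0);
#' one row per accession.
#' @param path Path to the label table.
#' @return data.frame with columns `domain_acc` (character) and
#'   `conserved` (logical).
#' @export
read_conservation <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  miss <- setdiff(c("domain_acc", "conserved"), names(tab))
  if (length(miss))
    stop2("conservation parse error in ", path, ": missing column(s): ",
          paste(miss, collapse = ", "))
  if (anyDuplicated(tab$domain_acc))
    stop2("conservation parse error in ", path,
          ": duplicated domain accession")
  conserved <- toupper(tab$conserved) %in% c("TRUE", "T", "1")
  data.frame(domain_acc = tab$domain_acc, conserved = conserved)
}

#' Write domain footprints as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so 1 is subtracted from the start only. Columns: chrom, start, end,
#' name (`domain_acc|protein_id`).
#'
#' @param footprints A footprint table from [domain_footprints()].
#' @param path Output path.
#' @export
write_bed <- function(footprints, path) {
  fp <- footprints$intervals %||% footprints
  bed <- data.frame(chrom = fp$chrom, start = fp$start - 1L, end = fp$end,
                    name = paste(fp$domain_acc, fp$protein_id, sep = "|"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a DCN edge list
#'
#' Tab-separated with header `from`, `to`, `support`. Round-trip stable:
#' `read_edge_list(write_edge_list(g, f))` reconstructs the same graph
#' (isolated nodes are kept on a trailing `#nodes:` comment line).
#'
#' @param dcn An igraph DCN from [build_dcn()].
#' @param path Output path.
#' @export
write_edge_list <- function(dcn, path) {
  el <- igraph::as_data_frame(dcn, what = "edges")
  if (is.null(el$support)) el$support <- rep(1L, nrow(el))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("from", "to", "support"), collapse = "\t"), con)
  if (nrow(el))
    writeLines(paste(el$from, el$to, el$support, sep = "\t"), con)
  iso <- setdiff(igraph::V(dcn)$name, unique(c(el$from, el$to)))
  if (length(iso))
    writeLines(paste0("#nodes: ", paste(iso, collapse = ",")), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  lines <- readLines(path)
  iso <- character()
  nl <- grep("^#nodes: ", lines, value = TRUE)
  if (length(nl))
    iso <- strsplit(sub("^#nodes: ", "", nl[1L]), ",", fixed = TRUE)[[1L]]
  lines <- lines[!grepl("^#", lines)]
  el <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          sep = "\t", colClasses = c("character",
                                                     "character",
                                                     "integer"))
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  g <- igraph::add_vertices(g, length(iso), name = iso)
  g
}

#' Write a result table as TSV
#'
#' @param x A data.frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Writers for the synthetic generator: same dialects the readers parse.

write_pfamscan <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pfam_scan-style domain hits",
               paste("# <seq id> <alignment start> <alignment end>",
                     "<envelope start> <envelope end> <hmm acc> <hmm name>",
                     "<type> <hmm start> <hmm end> <hmm length>",
                     "<bit score> <E-value>")), con)
  if (nrow(hits)) {
    len <- hits$pep_end - hits$pep_start + 1L
    writeLines(sprintf("%s %d %d %d %d %s %s Domain 1 %d %d %.1f %.3g",
                       hits$protein_id, hits$pep_start, hits$pep_end,
                       hits$pep_start, hits$pep_end, hits$domain_acc,
                       hits$domain_name, len, len, 100.0,
                       hits$e_value), con)
  }
  invisible(path)
}

write_gene_models <- function(models, path) {
  write_table(models, path)
}

write_maf <- function(rec, path) {
  maf <- data.frame(Hugo_Symbol = ".", Chromosome = rec$chrom,
                    Start_position = rec$position,
                    Reference_Allele = rec$ref_allele,
                    Tumor_Seq_Allele2 = rec$alt_allele,
                    Variant_Classification = rec$variant_classification,
                    Tumor_Sample_Barcode = rec$sample_id)
  write_table(maf, path)
}

write_conservation <- function(labels, path) {
  write_table(labels, path)
}
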