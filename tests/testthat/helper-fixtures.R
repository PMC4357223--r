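# Small in-code fixtures shared across test files.

make_hits <- function(protein_id, domain_acc, pep_start, pep_end,
                      e_value = 1e-10) {
  data.frame(protein_id = protein_id, domain_acc = domain_acc,
             domain_name = paste0("name_", domain_acc),
             pep_start = as.integer(pep_start),
             pep_end = as.integer(pep_end),
             e_value = rep_len(e_value, length(protein_id)))
}

make_model <- function(protein_id, chrom, strand, starts, ends,
                       gene_id = paste0("G_", protein_id)) {
  data.frame(gene_id = gene_id, protein_id = protein_id, chrom = chrom,
             strand = strand,
             cds_blocks = paste(paste0(starts, "-", ends),
                                collapse = ","))
}

make_mutations <- function(chrom, position,
                           classification = "Missense_Mutation",
                           sample_id = "S1") {
  n <- length(position)
  data.frame(chrom = rep_len(chrom, n), position = as.integer(position),
             ref_allele = rep_len("A", n), alt_allele = rep_len("G", n),
             variant_classification = rep_len(classification, n),
             sample_id = rep_len(sample_id, n),
             cancer_type = rep_len(NA_character_, n))
}

# a random gene model with 1..5 blocks whose total length is 3 * n_aa
random_model <- function(n_aa, protein_id = "P1", chrom = "7") {
  cds_len <- 3L * n_aa
  b <- sample(1:min(5L, cds_len), 1L)
  parts <- if (b == 1L) cds_len else {
    cuts <- sort(sample.int(cds_len - 1L, b - 1L))
    diff(c(0L, cuts, cds_len))
  }
  introns <- if (b > 1L) sample(10:200, b - 1L, replace = TRUE) else integer()
  start0 <- sample(1000:5000, 1L)
  starts <- start0 + cumsum(c(0L, parts[-b] + introns))
  ends <- starts + parts - 1L
  make_model(protein_id, chrom, sample(c("+", "-"), 1L), starts, ends)
}

# small end-to-end simulation config (fast, yet enough domains for the
# lfdr fit; used by profile and pipeline tests)
tiny_sim <- function(seed = 7L, n_hot = 5, ...) {
  sim_config(n_domains = 350, n_proteins = 900, baseline_rate = 0.03,
             n_hot = n_hot, seed = seed, ...)
}
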