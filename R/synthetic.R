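#' Simulation configuration
#'
#' Parameters of the synthetic study: a proteome whose domain-usage
#' frequencies are heavy-tailed (Zipf), so the resulting co-occurrence
#' network is scale-free-like with a deep nested core; gene models with
#' 1-5 CDS blocks on both strands; and a somatic point-mutation process
#' with a per-bp baseline rate, a stated fraction of Silent/RNA
#' records, a planted multiplicative depletion of mutation rate with
#' domain coreness, and optional planted hot domains at an elevated
#' rate.
#'
#' @param n_domains Number of domain families.
#' @param n_proteins Number of proteins (one gene/transcript each).
#' @param domain_usage_exponent Zipf exponent of domain popularity.
#' @param domains_per_protein Integer range `c(min, max)` of domain
#'   hits per protein.
#' @param cds_blocks_per_gene Integer range within `[1, 5]`.
#' @param domain_length_aa Integer range of domain family lengths (aa).
#' @param baseline_rate Mutations per coding bp.
#' @param core_depletion_beta Per-unit-coreness log-rate decrement:
#'   a domain of coreness k mutates at
#'   `baseline_rate * exp(-beta * k)`.
#' @param n_hot,hot_multiplier Number of planted hot domains and their
#'   rate multiplier (applied on top of the depletion factor).
#' @param silent_fraction,rna_fraction Fractions of records labeled
#'   Silent / RNA; their sum must be < 1.
#' @param conservation_base_prob,conservation_core_slope Conservation
#'   label model: `P(conserved | k) = clamp(base + slope * k, 0, 1)`.
#' @param bad_evalue_fraction Fraction of hits given an e-value in
#'   (0.01, 1] to exercise the construction filter.
#' @param n_samples Tumor sample barcodes to spread records over.
#' @param seed Integer seed; identical config + seed gives
#'   byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_domains = 1500, n_proteins = 4000,
                       domain_usage_exponent = 1.0,
                       domains_per_protein = c(1L, 4L),
                       cds_blocks_per_gene = c(1L, 5L),
                       domain_length_aa = c(40L, 200L),
                       baseline_rate = 0.03,
                       core_depletion_beta = 0.2,
                       n_hot = 25L, hot_multiplier = 10,
                       silent_fraction = 0.25, rna_fraction = 0.05,
                       conservation_base_prob = 0.2,
                       conservation_core_slope = 0.08,
                       bad_evalue_fraction = 0.05,
                       n_samples = 50L, seed = 1L) {
  cfg <- list(n_domains = as.integer(n_domains),
              n_proteins = as.integer(n_proteins),
              domain_usage_exponent = domain_usage_exponent,
              domains_per_protein = as.integer(domains_per_protein),
              cds_blocks_per_gene = as.integer(cds_blocks_per_gene),
              domain_length_aa = as.integer(domain_length_aa),
              baseline_rate = baseline_rate,
              core_depletion_beta = core_depletion_beta,
              n_hot = as.integer(n_hot), hot_multiplier = hot_multiplier,
              silent_fraction = silent_fraction,
              rna_fraction = rna_fraction,
              conservation_base_prob = conservation_base_prob,
              conservation_core_slope = conservation_core_slope,
              bad_evalue_fraction = bad_evalue_fraction,
              n_samples = as.integer(n_samples), seed = as.integer(seed))
  rng <- function(r, name, lo = 1L, hi = Inf) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < lo || r[2L] > hi)
      stop2("sim_config: invalid range for ", name, ": ",
            paste(r, collapse = ".."))
  }
  rng(cfg$domains_per_protein, "domains_per_protein")
  rng(cfg$cds_blocks_per_gene, "cds_blocks_per_gene", hi = 5L)
  rng(cfg$domain_length_aa, "domain_length_aa")
  if (cfg$n_domains < 1L || cfg$n_proteins < 1L)
    stop2("sim_config: counts must be >= 1")
  if (cfg$domain_usage_exponent <= 0)
    stop2("sim_config: domain_usage_exponent must be positive")
  if (cfg$baseline_rate <= 0) stop2("sim_config: baseline_rate must be > 0")
  if (cfg$core_depletion_beta < 0)
    stop2("sim_config: core_depletion_beta must be >= 0")
  frac <- c(cfg$silent_fraction, cfg$rna_fraction,
            cfg$conservation_base_prob, cfg$bad_evalue_fraction)
  if (any(frac < 0 | frac > 1)) stop2("sim_config: fractions must be in [0,1]")
  if (cfg$silent_fraction + cfg$rna_fraction >= 1)
    stop2("sim_config: silent_fraction + rna_fraction must be < 1")
  structure(cfg, class = "sim_config")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# sample n integers uniformly from lo..hi (safe when lo == hi)
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic proteome and its gene models
#'
#' Domain identities are drawn from a Zipf distribution so popular
#' domains co-occur with many partners; per-protein hits occupy
#' non-overlapping peptide intervals separated by linkers. Every
#' protein gets a gene model whose CDS blocks sum to exactly 3x its aa
#' length, non-overlapping within and between genes, strand uniform.
#' A `bad_evalue_fraction` of hits carries an e-value in (0.01, 1] so
#' the construction filter has something to remove.
#'
#' @param config A `sim_config`.
#' @return list with `hits` (domain hit table), `models` (gene model
#'   table), `domain_length_aa` (named vector of family lengths).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nd <- config$n_domains
  acc <- sprintf("PF%05d", seq_len(nd))
  dom_name <- sprintf("DOM_%04d", seq_len(nd))
  dlen <- sample_range(config$domain_length_aa[1L],
                       config$domain_length_aa[2L], nd)
  names(dlen) <- acc
  zipf_w <- seq_len(nd)^(-config$domain_usage_exponent)

  ndom <- sample_range(config$domains_per_protein[1L],
                       config$domains_per_protein[2L],
                       config$n_proteins)
  prot_id <- sprintf("PROT%05d", seq_len(config$n_proteins))
  dom_idx <- sample.int(nd, sum(ndom), replace = TRUE, prob = zipf_w)
  prot_of_hit <- rep(seq_len(config$n_proteins), ndom)
  hit_len <- dlen[dom_idx]
  # linkers: a gap before every domain and a tail after the last one
  gap <- sample(5:30, sum(ndom), replace = TRUE)
  tail_aa <- sample(5:30, config$n_proteins, replace = TRUE)
  # peptide layout per protein
  off <- unlist(lapply(split(gap + hit_len, prot_of_hit), cumsum),
                use.names = FALSE)
  pep_end <- off
  pep_start <- pep_end - hit_len + 1L
  prot_len <- vapply(split(pep_end, prot_of_hit), max, 0L) + tail_aa
  # divisible-by-3 is automatic (3 bp per aa); e-values
  n_hits <- sum(ndom)
  e_val <- 10^(-stats::runif(n_hits, 3, 30))
  n_bad <- round(config$bad_evalue_fraction * n_hits)
  if (n_bad > 0L) {
    bad <- sample.int(n_hits, n_bad)
    e_val[bad] <- stats::runif(n_bad, 0.0101, 1)
  }
  hits <- data.frame(protein_id = prot_id[prot_of_hit],
                     domain_acc = acc[dom_idx],
                     domain_name = dom_name[dom_idx],
                     pep_start = as.integer(pep_start),
                     pep_end = as.integer(pep_end),
                     e_value = signif(e_val, 6))

  # gene models: lay genes head-to-tail along chromosomes with gaps
  chroms <- c(as.character(1:22), "X")
  chrom <- sample(chroms, config$n_proteins, replace = TRUE)
  strand <- sample(c("+", "-"), config$n_proteins, replace = TRUE)
  cds_len <- 3L * as.integer(prot_len)
  nblk <- sample_range(config$cds_blocks_per_gene[1L],
                       config$cds_blocks_per_gene[2L],
                       config$n_proteins)
  nblk <- pmin(nblk, cds_len)  # at least 1 bp per block
  offset <- stats::setNames(rep(0L, length(chroms)), chroms)
  blocks_str <- character(config$n_proteins)
  for (i in seq_len(config$n_proteins)) {
    b <- nblk[i]
    # random composition of cds_len into b positive parts
    if (b == 1L) {
      parts <- cds_len[i]
    } else {
      cuts <- sort(sample.int(cds_len[i] - 1L, b - 1L))
      parts <- diff(c(0L, cuts, cds_len[i]))
    }
    introns <- if (b > 1L) sample(50:500, b - 1L, replace = TRUE) else integer()
    gstart <- offset[[chrom[i]]] + sample(100:1000, 1L)
    starts <- gstart + cumsum(c(0L, parts[-b] + introns))
    ends <- starts + parts - 1L
    offset[[chrom[i]]] <- ends[b]
    blocks_str[i] <- format_blocks(starts, ends)
  }
  models <- data.frame(gene_id = sprintf("GENE%05d",
                                         seq_len(config$n_proteins)),
                       protein_id = prot_id, chrom = chrom,
                       strand = strand, cds_blocks = blocks_str)
  list(hits = hits, models = models, domain_length_aa = dlen)
}

#' Generate somatic mutations with planted core-dependent depletion
#'
#' Point mutations are sampled region by region: each surviving domain
#' occurrence (e-value <= 0.01) mutates at
#' `baseline_rate * exp(-core_depletion_beta * coreness) *
#' hot_multiplier^[hot]` per bp, and non-domain coding sequence at the
#' baseline rate, with Poisson counts and uniform positions within the
#' region. A `silent_fraction` / `rna_fraction` of records is labeled
#' Silent / RNA (independently of position); the rest are
#' Missense/Nonsense. The returned truth object records the per-domain
#' relative rates actually used.
#'
#' @param hits,models Tables from [generate_proteome()].
#' @param coreness Named integer vector (domain -> core order) from a
#'   decomposition of the generated DCN; domains absent from it are
#'   treated as coreness 0 (outside the analyzed component).
#' @param config A `sim_config`.
#' @param hot_domains Optional explicit accession set; by default
#'   `config$n_hot` domains are sampled among domains present.
#' @return list with `mutations` (MAF-dialect table) and `truth`
#'   (class `synthetic_truth`: per-domain table of coreness,
#'   relative_rate, hot, plus the hot set).
#' @export
generate_mutations <- function(hits, models, coreness, config,
                               hot_domains = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "mutations"))
  keep <- hits$e_value <= 0.01
  hk <- hits[keep, , drop = FALSE]
  doms <- sort(unique(hk$domain_acc))
  cn <- stats::setNames(rep(0L, length(doms)), doms)
  known <- intersect(doms, names(coreness))
  cn[known] <- as.integer(coreness[known])
  if (length(known) < length(doms))
    message(length(doms) - length(known),
            " domain(s) without coreness treated as coreness 0")
  if (is.null(hot_domains)) {
    hot_domains <- if (config$n_hot > 0L)
      sample(doms, min(config$n_hot, length(doms))) else character()
  }
  # hot domains sit at hot_multiplier x baseline regardless of coreness;
  # everything else is depleted multiplicatively with core order
  rel_rate <- ifelse(doms %in% hot_domains, config$hot_multiplier,
                     exp(-config$core_depletion_beta * cn))
  names(rel_rate) <- doms

  # regions: every surviving domain occurrence, then non-domain coding
  fp <- domain_footprints(hk, models, e_value_max = 0.01)
  iv <- fp$intervals
  reg <- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                    rate = config$baseline_rate * rel_rate[iv$domain_acc])
  iv_by_prot <- split(iv, iv$protein_id)
  empty_iv <- iv[0L, , drop = FALSE]
  nd_reg <- lapply(seq_len(nrow(models)), function(i) {
    blocks <- gene_model_blocks(models[i, ])
    dom_iv <- iv_by_prot[[models$protein_id[i]]] %||% empty_iv
    comp <- subtract_intervals(blocks, dom_iv)
    if (nrow(comp) == 0L) return(NULL)
    data.frame(chrom = models$chrom[i], start = comp$start,
               end = comp$end, rate = config$baseline_rate)
  })
  nd_reg <- do.call(rbind, nd_reg[!vapply(nd_reg, is.null, TRUE)])
  reg <- rbind(reg, nd_reg)
  if (nrow(reg) == 0L || sum(reg$end - reg$start + 1) == 0)
    stop2("generate_mutations: empty coding footprint")

  len <- reg$end - reg$start + 1L
  counts <- stats::rpois(nrow(reg), len * reg$rate)
  idx <- rep(seq_len(nrow(reg)), counts)
  n <- length(idx)
  pos <- reg$start[idx] +
    floor(stats::runif(n) * len[idx])
  u <- stats::runif(n)
  sf <- config$silent_fraction; rf <- config$rna_fraction
  cls <- ifelse(u < sf, "Silent",
         ifelse(u < sf + rf, "RNA",
         ifelse(stats::runif(n) < 0.85, "Missense_Mutation",
                "Nonsense_Mutation")))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "",
                USE.NAMES = FALSE)
  mutations <- data.frame(
    chrom = reg$chrom[idx], position = as.integer(pos),
    ref_allele = ref, alt_allele = alt, variant_classification = cls,
    sample_id = sprintf("TCGA-SYN-%04d",
                        sample.int(config$n_samples, n, replace = TRUE)),
    cancer_type = NA_character_)
  mutations <- mutations[order(mutations$chrom, mutations$position), ]
  rownames(mutations) <- NULL
  truth <- structure(list(
    table = data.frame(domain_acc = doms, coreness = as.integer(cn),
                       relative_rate = as.numeric(rel_rate),
                       hot = doms %in% hot_domains),
    hot_domains = sort(hot_domains)), class = "synthetic_truth")
  list(mutations = mutations, truth = truth)
}

# blocks minus the union of domain intervals (all 1-based inclusive,
# same chromosome)
subtract_intervals <- function(blocks, dom_iv) {
  if (nrow(dom_iv) == 0L)
    return(data.frame(start = blocks$start, end = blocks$end))
  d <- dom_iv[order(dom_iv$start), , drop = FALSE]
  out_s <- integer(); out_e <- integer()
  for (b in seq_len(nrow(blocks))) {
    cur <- blocks$start[b]
    bend <- blocks$end[b]
    dd <- d[d$end >= cur & d$start <= bend, , drop = FALSE]
    for (j in seq_len(nrow(dd))) {
      if (dd$start[j] > cur) {
        out_s <- c(out_s, cur); out_e <- c(out_e, dd$start[j] - 1L)
      }
      cur <- max(cur, dd$end[j] + 1L)
    }
    if (cur <= bend) {
      out_s <- c(out_s, cur); out_e <- c(out_e, bend)
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Generate conservation labels correlated with coreness
#'
#' Each domain is conserved with probability
#' `clamp(conservation_base_prob + conservation_core_slope * k, 0, 1)`.
#'
#' @param coreness Named integer vector (domain -> core order).
#' @param config A `sim_config`.
#' @return data.frame `domain_acc`, `conserved` (logical).
#' @export
generate_conservation_labels <- function(coreness, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "conservation"))
  p <- clamp01(config$conservation_base_prob +
               config$conservation_core_slope * as.numeric(coreness))
  data.frame(domain_acc = names(coreness),
             conserved = stats::rbinom(length(coreness), 1L, p) == 1L)
}

#' Run the whole synthetic study in memory
#'
#' Convenience wrapper: proteome -> DCN -> largest component -> k-core
#' decomposition -> conservation labels -> mutations with planted
#' depletion. Domains outside the largest component get coreness 0 for
#' the generation step.
#'
#' @param config A `sim_config`.
#' @return list with `hits`, `models`, `dcn` (largest component),
#'   `decomposition`, `coreness_all` (every surviving domain, zeros for
#'   non-component domains), `conservation`, `mutations`, `truth`.
#' @export
synthesize_study <- function(config = sim_config()) {
  prot <- generate_proteome(config)
  g <- build_dcn(prot$hits, e_value_max = 0.01)
  main <- largest_component(g)
  dec <- kcore_decompose(main)
  doms <- sort(unique(prot$hits$domain_acc[prot$hits$e_value <= 0.01]))
  cn_all <- stats::setNames(rep(0L, length(doms)), doms)
  cn_all[names(dec$coreness)] <- dec$coreness
  cons <- generate_conservation_labels(cn_all, config)
  mut <- suppressMessages(
    generate_mutations(prot$hits, prot$models, cn_all, config))
  list(hits = prot$hits, models = prot$models, dcn = main,
       decomposition = dec, coreness_all = cn_all, conservation = cons,
       mutations = mut$mutations, truth = mut$truth)
}
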