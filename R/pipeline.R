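#' Pipeline run configuration
#'
#' Collects the paths, thresholds and seeds every pipeline stage needs.
#' `conditions` names the mutation sets (e.g. cancer types); in
#' simulation mode one MAF-dialect file is generated per condition.
#'
#' @param outdir Output/working directory (artifacts of one run).
#' @param conditions Character vector of condition labels.
#' @param e_value_max Domain-hit e-value cutoff (default 0.01).
#' @param n_replicates Randomized cores per ensemble (default 100).
#' @param lfdr_threshold,lfdr_bins,lfdr_degree,lfdr_null_method,lfdr_transform
#'   Local-fdr settings (defaults 0.1, 120, 7, central-matching,
#'   identity).
#' @param seed Global seed; per-stage seeds are derived by fixed
#'   offsets.
#' @param sim A `sim_config` used by [cmd_simulate()].
#' @param hits,models,conservation Optional input paths when not
#'   simulating; `mutations` a named list of MAF paths per condition.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, conditions = "tumor", e_value_max = 0.01,
                       n_replicates = 100, lfdr_threshold = 0.1,
                       lfdr_bins = 120, lfdr_degree = 7,
                       lfdr_null_method = "central-matching",
                       lfdr_transform = "identity", seed = 1L,
                       sim = sim_config(seed = seed), hits = NULL,
                       models = NULL, conservation = NULL,
                       mutations = NULL) {
  if (length(conditions) < 1L) stop2("run_config: conditions nonempty")
  if (e_value_max <= 0 || lfdr_threshold <= 0 || n_replicates < 1L)
    stop2("run_config: thresholds must be positive")
  structure(list(outdir = outdir, conditions = conditions,
                 e_value_max = e_value_max, n_replicates = n_replicates,
                 lfdr_threshold = lfdr_threshold, lfdr_bins = lfdr_bins,
                 lfdr_degree = lfdr_degree,
                 lfdr_null_method = lfdr_null_method,
                 lfdr_transform = lfdr_transform,
                 seed = as.integer(seed), sim = sim, hits = hits,
                 models = models, conservation = conservation,
                 mutations = mutations),
            class = "run_config")
}

art <- function(cfg, ...) file.path(cfg$outdir, paste0(...))

need_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop2("missing artifact ", path, "; run `", producer, "` first")
  path
}

input_path <- function(cfg, key, default, condition = NULL) {
  p <- if (is.null(condition)) cfg[[key]] else cfg[[key]][[condition]]
  p %||% default
}

# 32-bit FNV-1a over a string; used only to fingerprint configs in the
# run manifest.
fnv1a <- function(s) {
  b <- utf8ToInt(s)
  h <- 216613626
  for (x in b) {
    h <- bitwXor(as.integer(h %% 2^31), x) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

config_hash <- function(cfg) {
  fnv1a(jsonlite::toJSON(unclass(cfg)[setdiff(names(cfg), "outdir")],
                         auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE))
}

#' Pipeline stages
#'
#' Each `cmd_*` stage reads its upstream artifacts from
#' `config$outdir` (or the configured external input paths), writes
#' its own TSV artifacts there, and is idempotent given identical
#' inputs and seed. [cmd_run_all()] chains all stages and writes a
#' `manifest.json` recording the package version, config hash and
#' seeds.
#'
#' @param config A `run_config`.
#' @return Invisibly, the main object(s) the stage produced.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  study <- synthesize_study(config$sim)
  write_pfamscan(study$hits, art(config, "hits.pfamscan.txt"))
  write_gene_models(study$models, art(config, "gene_models.tsv"))
  write_conservation(study$conservation, art(config, "conservation.tsv"))
  truths <- list()
  for (i in seq_along(config$conditions)) {
    cond <- config$conditions[i]
    if (i == 1L) {
      mut <- list(mutations = study$mutations, truth = study$truth)
    } else {
      cfg_i <- config$sim
      cfg_i$seed <- config$sim$seed + i - 1L
      mut <- suppressMessages(generate_mutations(
        study$hits, study$models, study$coreness_all, cfg_i,
        hot_domains = study$truth$hot_domains))
    }
    mut$mutations$cancer_type <- cond
    write_maf(mut$mutations, art(config, "mutations_", cond, ".maf.tsv"))
    truths[[cond]] <- list(
      hot_domains = mut$truth$hot_domains,
      relative_rate = stats::setNames(
        as.list(mut$truth$table$relative_rate),
        mut$truth$table$domain_acc))
  }
  jsonlite::write_json(truths, art(config, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(study)
}

#' @rdname pipeline
#' @export
cmd_build <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hp <- input_path(config, "hits", art(config, "hits.pfamscan.txt"))
  need_artifact(hp, "simulate")
  hits <- read_pfamscan(hp)
  g <- build_dcn(hits, e_value_max = config$e_value_max)
  main <- largest_component(g)
  write_edge_list(g, art(config, "dcn_full.edges.tsv"))
  write_edge_list(main, art(config, "dcn_main.edges.tsv"))
  st <- network_stats(main)
  write_table(st$degree_distribution, art(config, "degree_distribution.tsv"))
  write_table(st$clustering_by_degree,
              art(config, "clustering_by_degree.tsv"))
  write_table(st$path_length_histogram,
              art(config, "path_length_histogram.tsv"))
  message("DCN: ", igraph::vcount(g), " nodes / ", igraph::ecount(g),
          " edges; largest component ", igraph::vcount(main), " / ",
          igraph::ecount(main))
  invisible(main)
}

#' @rdname pipeline
#' @export
cmd_decompose <- function(config) {
  main <- read_edge_list(need_artifact(art(config, "dcn_main.edges.tsv"),
                                       "build"))
  dec <- kcore_decompose(main)
  write_table(data.frame(domain_acc = names(dec$coreness),
                         coreness = as.integer(dec$coreness)),
              art(config, "coreness.tsv"))
  invisible(dec)
}

read_coreness <- function(config) {
  tab <- utils::read.delim(need_artifact(art(config, "coreness.tsv"),
                                         "decompose"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$coreness, tab$domain_acc)
}

#' @rdname pipeline
#' @export
cmd_map <- function(config) {
  hp <- need_artifact(input_path(config, "hits",
                                 art(config, "hits.pfamscan.txt")),
                      "simulate")
  mp <- need_artifact(input_path(config, "models",
                                 art(config, "gene_models.tsv")),
                      "simulate")
  hits <- read_pfamscan(hp)
  models <- read_gene_models(mp)
  fp <- domain_footprints(hits, models, e_value_max = config$e_value_max)
  write_bed(fp, art(config, "footprints.bed"))
  out <- list(footprints = fp, counts = list())
  for (cond in config$conditions) {
    mfp <- need_artifact(
      input_path(config, "mutations",
                 art(config, "mutations_", cond, ".maf.tsv"), cond),
      "simulate")
    rec <- read_maf(mfp, cancer_type = cond)
    rec <- suppressMessages(filter_mutations(rec))
    cnt <- map_mutations(rec, fp)
    write_table(cnt$counts, art(config, "counts_", cond, ".tsv"))
    write_table(data.frame(condition = cond, M = cnt$M,
                           mapped = cnt$mapped,
                           mapped_percentage = cnt$mapped_percentage),
                art(config, "mapping_summary_", cond, ".tsv"))
    out$counts[[cond]] <- cnt
  }
  invisible(out)
}

read_counts <- function(config, cond, fp) {
  tab <- utils::read.delim(need_artifact(art(config, "counts_", cond,
                                             ".tsv"), "map"),
                           colClasses = c("character", "integer"))
  structure(list(counts = tab, M = NA_integer_, mapped = sum(tab$m),
                 mapped_percentage = NA_real_),
            class = "domain_mutation_counts")
}

#' @rdname pipeline
#' @export
cmd_stats <- function(config) {
  hits <- read_pfamscan(need_artifact(
    input_path(config, "hits", art(config, "hits.pfamscan.txt")),
    "simulate"))
  models <- read_gene_models(need_artifact(
    input_path(config, "models", art(config, "gene_models.tsv")),
    "simulate"))
  fp <- domain_footprints(hits, models, e_value_max = config$e_value_max)
  sig <- list()
  stats_objs <- list()
  for (cond in config$conditions) {
    cnt <- read_counts(config, cond, fp)
    st <- suppressMessages(domain_stats(
      cnt, fp, lfdr_threshold = config$lfdr_threshold,
      bins = config$lfdr_bins, poly_degree = config$lfdr_degree,
      null_method = config$lfdr_null_method,
      transform = config$lfdr_transform))
    write_table(st$table, art(config, "stats_", cond, ".tsv"))
    sig[[cond]] <- call_significant(st, config$lfdr_threshold)
    stats_objs[[cond]] <- st
  }
  if (length(sig) >= 2L) {
    ov <- overlap_sets(sig)
    write_table(ov$regions, art(config, "overlap_regions.tsv"))
    writeLines(ov$intersection, art(config, "overlap_intersection.txt"))
  }
  invisible(stats_objs)
}

#' @rdname pipeline
#' @export
cmd_profile <- function(config) {
  main <- read_edge_list(need_artifact(art(config, "dcn_main.edges.tsv"),
                                       "build"))
  dec <- kcore_decompose(main)
  ens <- random_core_ensembles(main, dec,
                               n_replicates = config$n_replicates,
                               seed = stage_seed(config$seed, "profile"))
  cons_path <- input_path(config, "conservation",
                          art(config, "conservation.tsv"))
  cons <- if (file.exists(cons_path)) read_conservation(cons_path) else NULL
  hits <- read_pfamscan(need_artifact(
    input_path(config, "hits", art(config, "hits.pfamscan.txt")),
    "simulate"))
  models <- read_gene_models(need_artifact(
    input_path(config, "models", art(config, "gene_models.tsv")),
    "simulate"))
  fp <- domain_footprints(hits, models, e_value_max = config$e_value_max)
  summaries <- list()
  for (cond in config$conditions) {
    stab <- utils::read.delim(need_artifact(art(config, "stats_", cond,
                                                ".tsv"), "stats"))
    stab$domain_acc <- as.character(stab$domain_acc)
    prof <- suppressMessages(profile_cores(
      dec, ens, stab, conservation = cons,
      significant = stab$domain_acc[stab$significant]))
    write_table(prof$table, art(config, "core_profile_", cond, ".tsv"))
    tt <- trend_test(prof, "mean_s")
    cnt <- read_counts(config, cond, fp)
    gof <- chi_square_cores(dec, fp, cnt)
    write_table(gof$table, art(config, "core_gof_", cond, ".tsv"))
    summaries[[cond]] <- data.frame(
      condition = cond, trend_rho = tt$statistic,
      trend_p = tt$p_empirical, trend_direction = tt$direction,
      gof_statistic = gof$statistic, gof_df = gof$df,
      gof_p = gof$p_value)
  }
  summary <- do.call(rbind, summaries)
  write_table(summary, art(config, "core_tests_summary.tsv"))
  invisible(summary)
}

#' @rdname pipeline
#' @export
cmd_run_all <- function(config) {
  simulate <- is.null(config$hits)
  if (simulate) cmd_simulate(config)
  cmd_build(config)
  cmd_decompose(config)
  cmd_map(config)
  cmd_stats(config)
  out <- cmd_profile(config)
  manifest <- list(
    package = "dcnmut",
    version = as.character(utils::packageVersion("dcnmut")),
    config_hash = config_hash(config), seed = config$seed,
    conditions = config$conditions, simulated = simulate)
  jsonlite::write_json(manifest, art(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
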