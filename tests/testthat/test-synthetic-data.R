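test_that("config validation rejects impossible settings", {
  expect_error(sim_config(domains_per_protein = c(3, 2)), "range")
  expect_error(sim_config(cds_blocks_per_gene = c(1, 9)), "range")
  expect_error(sim_config(silent_fraction = 0.7, rna_fraction = 0.4),
               "< 1")
  expect_error(sim_config(baseline_rate = 0), "baseline_rate")
  expect_error(sim_config(core_depletion_beta = -1), "beta")
  expect_error(sim_config(n_domains = 0), "counts")
})

test_that("proteome counts are forced by the config", {
  cfg <- sim_config(n_domains = 10, n_proteins = 2,
                    domains_per_protein = c(2, 2), n_hot = 0, seed = 3)
  p <- generate_proteome(cfg)
  expect_equal(nrow(p$hits), 4L)
  expect_equal(nrow(p$models), 2L)
})

test_that("CDS length equals 3x protein length; blocks valid; hits disjoint", {
  cfg <- tiny_sim(seed = 5)
  p <- generate_proteome(cfg)
  for (i in seq_len(nrow(p$models))) {
    blocks <- gene_model_blocks(p$models[i, ])
    check_ok <- tryCatch({
      dcnmut:::check_blocks(blocks); TRUE
    }, error = function(e) FALSE)
    expect_true(check_ok)
    hit_i <- p$hits[p$hits$protein_id == p$models$protein_id[i], ]
    cds_aa <- sum(blocks$end - blocks$start + 1L) / 3L
    expect_gte(cds_aa, max(hit_i$pep_end))
    # non-overlapping peptide intervals
    o <- order(hit_i$pep_start)
    if (nrow(hit_i) > 1L)
      expect_true(all(hit_i$pep_start[o][-1L] >
                        hit_i$pep_end[o][-nrow(hit_i)]))
  }
  # e-values: mostly <= 0.01 with an injected bad fraction
  expect_gt(mean(p$hits$e_value <= 0.01), 0.9)
  expect_gt(sum(p$hits$e_value > 0.01), 0L)
})

test_that("generator is deterministic under its seed", {
  p1 <- generate_proteome(tiny_sim(seed = 11))
  p2 <- generate_proteome(tiny_sim(seed = 11))
  expect_identical(p1, p2)
  s1 <- synthesize_study(tiny_sim(seed = 11))
  s2 <- synthesize_study(tiny_sim(seed = 11))
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$conservation, s2$conservation)
})

test_that("every mutation lies inside a CDS block of some gene", {
  st <- synthesize_study(tiny_sim(seed = 2))
  blocks <- do.call(rbind, lapply(seq_len(nrow(st$models)), function(i) {
    b <- gene_model_blocks(st$models[i, ])
    b$chrom <- st$models$chrom[i]
    b
  }))
  bl_gr <- GenomicRanges::GRanges(blocks$chrom,
                                  IRanges::IRanges(blocks$start,
                                                   blocks$end))
  mu_gr <- GenomicRanges::GRanges(st$mutations$chrom,
                                  IRanges::IRanges(st$mutations$position,
                                                   st$mutations$position))
  expect_equal(sum(GenomicRanges::countOverlaps(mu_gr, bl_gr) == 0), 0L)
  expect_true(all(st$mutations$ref_allele != st$mutations$alt_allele))
})

test_that("silent fraction is honoured within binomial bounds", {
  cfg <- sim_config(n_domains = 150, n_proteins = 600,
                    baseline_rate = 0.03, silent_fraction = 0.3,
                    rna_fraction = 0.05, core_depletion_beta = 0,
                    n_hot = 0, seed = 8)
  st <- synthesize_study(cfg)
  n <- nrow(st$mutations)
  expect_gt(n, 10000)
  frac <- mean(st$mutations$variant_classification == "Silent")
  band <- 2.58 * sqrt(0.3 * 0.7 / n)  # binomial 99% interval
  expect_lt(abs(frac - 0.3), band)
})

test_that("beta = 0 gives footprint-proportional counts; hot domains 10x", {
  cfg <- sim_config(n_domains = 60, n_proteins = 500,
                    baseline_rate = 0.01, core_depletion_beta = 0,
                    silent_fraction = 0, rna_fraction = 0,
                    n_hot = 1, hot_multiplier = 10, seed = 13)
  p <- generate_proteome(cfg)
  cn <- stats::setNames(rep(1L, cfg$n_domains),
                        sprintf("PF%05d", 1:cfg$n_domains))
  gen <- suppressMessages(
    generate_mutations(p$hits, p$models, cn, cfg))
  fp <- domain_footprints(p$hits, p$models)
  cnt <- map_mutations(gen$mutations, fp)
  m <- stats::setNames(cnt$counts$m, cnt$counts$domain_acc)
  L <- fp$cumulative_length[names(m)]
  hot <- gen$truth$hot_domains
  expect_length(hot, 1L)
  # Poisson 99% check for the hot domain at 10x baseline
  lam_hot <- 10 * cfg$baseline_rate * L[hot]
  expect_lt(abs(m[hot] - lam_hot), 2.58 * sqrt(lam_hot) + 3)
  # non-hot: observed total rate ~ baseline; per-domain densities flat.
  # mapped counts can exceed the domain-own expectation where footprints
  # of different domains overlap, so test the aggregate rate loosely
  nh <- setdiff(names(m), hot)
  rate <- sum(m[nh]) / sum(as.numeric(L[nh]))
  expect_lt(abs(rate - cfg$baseline_rate) / cfg$baseline_rate, 0.25)
  # truth records the rates actually used
  expect_true(all(gen$truth$table$relative_rate[
    gen$truth$table$domain_acc == hot] == 10))
  expect_true(all(gen$truth$table$relative_rate[
    !gen$truth$table$hot] == 1))
})

test_that("conservation labels follow the clamped linear model", {
  cfg <- sim_config(conservation_base_prob = 0.2,
                    conservation_core_slope = 0.08, seed = 4)
  k <- rep(0:10, each = 800)
  cn <- stats::setNames(as.integer(k), sprintf("D%05d", seq_along(k)))
  lab <- generate_conservation_labels(cn, cfg)
  frac <- tapply(lab$conserved, k, mean)
  expected <- pmin(1, 0.2 + 0.08 * (0:10))
  expect_true(all(abs(frac - expected) < 0.06))
  # k = 10 clamps to probability 1.0
  expect_equal(unname(frac["10"]), 1)
  # monotone increasing in k up to sampling noise
  expect_true(all(diff(frac) > -0.05))
  # slope 0: flat at base prob
  cfg0 <- sim_config(conservation_core_slope = 0, seed = 4)
  lab0 <- generate_conservation_labels(cn, cfg0)
  frac0 <- tapply(lab0$conserved, k, mean)
  expect_true(all(abs(frac0 - 0.2) < 0.06))
})

test_that("planted depletion produces a decreasing per-core density", {
  st <- synthesize_study(sim_config(n_domains = 400, n_proteins = 1200,
                                    core_depletion_beta = 0.3,
                                    n_hot = 0, seed = 21))
  rec <- suppressMessages(filter_mutations(st$mutations))
  fp <- domain_footprints(st$hits, st$models)
  cnt <- map_mutations(rec, fp)
  m <- stats::setNames(cnt$counts$m, cnt$counts$domain_acc)
  cn <- st$decomposition$coreness
  shared <- intersect(names(cn), names(m))
  dens <- tapply(m[shared], cn[shared], sum) /
    tapply(as.numeric(fp$cumulative_length[shared]), cn[shared], sum)
  ct <- suppressWarnings(
    cor.test(as.integer(names(dens)), dens, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
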