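test_that("single-block conversion on both strands matches hand values", {
  model_p <- make_model("P1", "7", "+", 1001L, 1900L)
  model_m <- make_model("P1", "7", "-", 1001L, 1900L)
  hit <- make_hits("P1", "PF1", 1, 10)
  expect_equal(peptide_to_genomic(hit, model_p),
               data.frame(chrom = "7", start = 1001L, end = 1030L))
  expect_equal(peptide_to_genomic(hit, model_m),
               data.frame(chrom = "7", start = 1871L, end = 1900L))
})

test_that("multi-block conversion matches the per-base oracle", {
  model <- make_model("P1", "2", "+", c(100L, 200L), c(129L, 259L))
  hit <- make_hits("P1", "PF1", 6, 15)
  iv <- peptide_to_genomic(hit, model)
  expect_equal(iv$start, c(115L, 200L))
  expect_equal(iv$end, c(129L, 214L))
  oracle <- oracle_residue_positions(gene_model_blocks(model), "+", 6, 15)
  expect_equal(expand_intervals(iv), oracle)
})

test_that("conversion errors on mismatched protein or overlong domain", {
  model <- make_model("P2", "1", "+", 1L, 300L)
  expect_error(peptide_to_genomic(make_hits("P1", "PF1", 1, 10), model),
               "does not match")
  model2 <- make_model("P1", "1", "+", 1L, 30L)
  expect_error(peptide_to_genomic(make_hits("P1", "PF1", 1, 11), model2),
               "extends past CDS")
})

test_that("randomized models: oracle equivalence and round trip", {
  set.seed(21)
  for (i in 1:60) {
    n_aa <- sample(20:120, 1)
    model <- random_model(n_aa)
    blocks <- gene_model_blocks(model)
    strand <- model$strand
    ps <- sample.int(n_aa - 4L, 1L)
    pe <- min(n_aa, ps + sample(0:20, 1L))
    iv <- peptide_to_genomic(make_hits("P1", "PF1", ps, pe), model)
    # sum of interval lengths = 3 * residue count
    expect_equal(sum(iv$end - iv$start + 1L), 3L * (pe - ps + 1L))
    # per-base oracle equivalence
    expect_equal(expand_intervals(iv),
                 oracle_residue_positions(blocks, strand, ps, pe))
    # round trip: each residue's codon maps back to the residue index
    cds <- enumerate_cds(blocks, strand)
    for (r in c(ps, pe)) {
      codon <- peptide_to_genomic(make_hits("P1", "PF1", r, r), model)
      nt_idx <- match(expand_intervals(codon), cds)
      expect_equal(sort(nt_idx), (3L * (r - 1L) + 1L):(3L * r))
    }
  }
})

test_that("filter_mutations drops Silent and RNA case-insensitively", {
  rec <- make_mutations("1", 1:4,
                        classification = c("Missense_Mutation", "Silent",
                                           "RNA", "Nonsense_Mutation"))
  out <- suppressMessages(filter_mutations(rec))
  expect_equal(out$variant_classification,
               c("Missense_Mutation", "Nonsense_Mutation"))
  rec2 <- make_mutations("1", 1:2, classification = c("silent", "rna"))
  expect_equal(nrow(suppressMessages(filter_mutations(rec2))), 0L)
  expect_equal(nrow(suppressMessages(filter_mutations(rec[0, ]))), 0L)
})

test_that("map_mutations counts overlaps with inclusive bounds", {
  fp <- structure(list(intervals = data.frame(
    domain_acc = c("PF1", "PF2", "PF2"),
    protein_id = c("P1", "P1", "P2"),
    chrom = c("1", "1", "2"),
    start = c(100L, 150L, 500L), end = c(199L, 249L, 599L)),
    cumulative_length = c(PF1 = 100L, PF2 = 200L)),
    class = "domain_footprints")
  rec <- make_mutations(c("1", "1", "1", "2"),
                        c(199L, 160L, 300L, 599L))
  cnt <- map_mutations(rec, fp)
  # pos 199 is the inclusive boundary of PF1 and inside PF2; 160 inside
  # PF1+PF2; 300 unmapped; 599 boundary of PF2's second occurrence
  expect_equal(cnt$counts$m[cnt$counts$domain_acc == "PF1"], 2L)
  expect_equal(cnt$counts$m[cnt$counts$domain_acc == "PF2"], 3L)
  expect_equal(cnt$mapped, 3L)
  expect_equal(cnt$M, 4L)
  expect_equal(cnt$mapped_percentage, 75)
})

test_that("double-counted domains still map once to the total", {
  fp <- structure(list(intervals = data.frame(
    domain_acc = c("A", "B"), protein_id = "P1", chrom = "1",
    start = c(100L, 100L), end = c(200L, 200L)),
    cumulative_length = c(A = 101L, B = 101L)),
    class = "domain_footprints")
  cnt <- map_mutations(make_mutations("1", 150L), fp)
  expect_equal(sum(cnt$counts$m), 2L)
  expect_equal(cnt$mapped, 1L)
})

test_that("random fixtures match the linear-scan oracle; order invariant", {
  for (seed in 1:10) {
    set.seed(seed)
    n_dom <- 6
    iv <- data.frame(
      domain_acc = sample(paste0("PF", 1:n_dom), 15, replace = TRUE),
      protein_id = sample(paste0("P", 1:5), 15, replace = TRUE),
      chrom = sample(c("1", "2"), 15, replace = TRUE),
      start = sample(1:900, 15))
    iv$end <- iv$start + sample(10:80, 15, replace = TRUE)
    cum <- tapply(iv$end - iv$start + 1L, iv$domain_acc, sum)
    fp <- structure(list(intervals = iv,
                         cumulative_length = stats::setNames(
                           as.integer(cum), names(cum))),
                    class = "domain_footprints")
    rec <- make_mutations(sample(c("1", "2"), 200, replace = TRUE),
                          sample(1:1000, 200, replace = TRUE))
    cnt <- map_mutations(rec, fp)
    oracle <- oracle_map(rec, fp)
    expect_equal(stats::setNames(cnt$counts$m, cnt$counts$domain_acc),
                 oracle$m[cnt$counts$domain_acc])
    expect_equal(cnt$mapped, oracle$mapped)
    cnt2 <- map_mutations(rec[sample(nrow(rec)), ], fp)
    expect_equal(cnt2$counts, cnt$counts)
    expect_equal(cnt2$mapped, cnt$mapped)
  }
})

test_that("footprint cumulative length sums interval lengths", {
  hits <- make_hits(c("P1", "P2"), c("PF1", "PF1"), c(1, 5), c(10, 14))
  models <- rbind(make_model("P1", "1", "+", 1L, 60L),
                  make_model("P2", "1", "-", 1001L, 1090L))
  fp <- domain_footprints(hits, models)
  expect_equal(unname(fp$cumulative_length["PF1"]), 60L)
  expect_equal(sum(fp$intervals$end - fp$intervals$start + 1L), 60L)
})
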