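test_that("genome panels are deterministic under a fixed seed", {
  cfg <- pea_screen_config(5L)
  p1 <- sim_genome_panel(cfg)
  p2 <- sim_genome_panel(cfg)
  expect_identical(p1$reference$seq, p2$reference$seq)
  expect_identical(lapply(p1$genomes, `[[`, "seq"),
                   lapply(p2$genomes, `[[`, "seq"))
  expect_identical(p1$truth$variants, p2$truth$variants)
  expect_false(identical(sim_genome_panel(pea_screen_config(6L))$reference$seq,
                         p1$reference$seq))
})

test_that("zero planted variants give queries identical to the reference", {
  cfg <- pea_screen_config(2L)
  cfg$variants <- cfg$variants[0, , drop = FALSE]
  p <- sim_genome_panel(cfg)
  for (g in p$genomes) expect_identical(g$seq, p$reference$seq)
  expect_identical(nrow(p$truth$variants), 0L)
})

test_that("planted variants are recovered exactly by the caller (round trip)", {
  run <- get_screen_run(1L)
  tr <- run$panel$truth
  cols <- c("ref_start", "ref_end", "type", "ref_allele", "alt_allele",
            "locus", "region", "effect")
  for (acc in names(run$calls)) {
    want <- tr$variants[tr$present[, acc], cols]
    got <- run$calls[[acc]][, cols]
    want <- want[order(want$ref_start, want$ref_end), ]
    got <- got[order(got$ref_start, got$ref_end), ]
    rownames(want) <- rownames(got) <- NULL
    expect_identical(got, want, info = acc)
  }
})

test_that("the generated panel feeds the whole screening funnel", {
  run <- get_screen_run(1L)
  pm <- build_presence_matrix(run$calls, run$panel$reference$id,
                              run$panel$phenotypes)
  filt <- pattern_filter(pm)
  fun <- funnel_summary(filt)
  expect_identical(fun$n_total, 37L)
  expect_identical(fun$n_noncoding, 15L)
  expect_identical(fun$n_noncoding_regions, 14L)
  expect_identical(fun$n_coding_loci, 7L)
  expect_identical(fun$n_synonymous, 5L)
  expect_identical(fun$n_nonsyn_substitutions, 14L)
  expect_identical(fun$n_indels, 3L)
  cand <- nominate_loci(filt)
  expect_identical(nrow(cand), 4L)
  expect_identical(cand$locus[1], "accD")
  expect_identical(cand$n_nonsyn_substitutions[1], 8L)
  expect_identical(cand$n_indels[1], 3L)
})

test_that("fixture-mode RIL generation reproduces requested crossover patterns", {
  sim <- sim_ril_population(
    0, c("PhlC", "Bccp3", "AJ832139"), r = c(0, 0),
    patterns = c(AAA = 42L, BBB = 41L, AAB = 2L, BBA = 1L, ABB = 1L,
                 BAA = 1L))
  expect_identical(nrow(sim$table), 88L)
  expect_identical(
    recombinant_count(sim$table, "PhlC", "AJ832139")$n_recombinant, 5L)
  expect_identical(
    recombinant_count(sim$table, "Bccp3", "AJ832139")$n_recombinant, 3L)
  expect_identical(
    recombinant_count(sim$table, "PhlC", "Bccp3")$n_recombinant, 2L)
})

test_that("simulated cross panels equal the rule closure of their truth genotypes", {
  sim <- sim_cross_panel(n_accessions = 5L, seed = 17L)
  expect_identical(sim$outcomes, forward_panel(sim$genotypes))
  expect_identical(nrow(sim$outcomes), 25L)
  # self-compatible sampling keeps all selfs compatible
  selfs <- sim$outcomes[sim$outcomes$cytoplasm_donor ==
                          sim$outcomes$nuclear_donor, ]
  expect_true(all(selfs$outcome == "compatible"))
  # determinism
  expect_identical(sim_cross_panel(5L, seed = 17L)$outcomes, sim$outcomes)
})
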