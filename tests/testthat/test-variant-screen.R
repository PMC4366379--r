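test_that("align_and_call returns no variants for identical genomes", {
  run <- get_screen_run(1L)
  ref <- run$panel$reference
  twin <- annotated_genome("TWIN", ref$seq)
  expect_identical(nrow(align_and_call(ref, twin)), 0L)
})

test_that("a planted substitution is called at its coordinate with its effect", {
  cds <- paste0("ATG", "GCTACCGATCTTGGTCGTACCAAT", "TAA")  # no internal stop
  g <- one_cds_genome(cds)
  # A->G at a CDS position (codon 2 first base: G->A changes Ala->Thr)
  p <- 8L + 3L  # flank5 (7) + codon2 start
  expect_identical(substr(g$seq, p, p), "G")
  q <- g$seq; substr(q, p, p) <- "A"
  # pad with unique flanks so anchors exist
  withr::local_seed(11)
  pad5 <- random_protein(120, c("A", "C", "G", "T"))
  pad3 <- random_protein(120, c("A", "C", "G", "T"))
  ref2 <- annotated_genome("R", paste0(pad5, g$seq, pad3), data.frame(
    locus = "cdsA", kind = "CDS", start = 120L + 8L,
    end = 120L + 7L + nchar(cds), strand = "+", phase = 0L))
  qry <- annotated_genome("Q", paste0(pad5, q, pad3))
  v <- align_and_call(ref2, qry)
  expect_identical(nrow(v), 1L)
  expect_identical(v$ref_start, 120L + p)
  expect_identical(v$type, "substitution")
  expect_identical(v$ref_allele, "G")
  expect_identical(v$alt_allele, "A")
  expect_identical(v$effect, "nonsynonymous")
})

test_that("a deletion removing the start codon is called as start_loss", {
  # 21-bp deletion spanning the 5' untranslated region and the start codon
  withr::local_seed(21)
  pad5 <- random_protein(150, c("A", "C", "G", "T"))
  pad3 <- random_protein(150, c("A", "C", "G", "T"))
  cds <- paste0("ATG", strrep("GCTAACGAT", 8), "TAA")
  ref <- annotated_genome("R", paste0(pad5, cds, pad3), data.frame(
    locus = "cdsA", kind = "CDS", start = 151L, end = 150L + nchar(cds),
    strand = "+", phase = 0L))
  # delete positions 133..153: last 18 bases of the 5' flank + ATG
  del_s <- 133L; del_e <- 153L
  q <- paste0(substr(ref$seq, 1, del_s - 1L),
              substr(ref$seq, del_e + 1L, nchar(ref$seq)))
  v <- align_and_call(ref, annotated_genome("Q", q))
  del <- v[v$type == "deletion", , drop = FALSE]
  expect_identical(nrow(del), 1L)
  expect_identical(del$ref_end - del$ref_start + 1L, 21L)
  expect_identical(del$effect, "start_loss")
  expect_identical(del$region, "CDS")
})

test_that("classify_effect follows the plastid-code rules", {
  cds <- paste0("ATG", "GCTACCGATCTTGGTCGTACCAAT", "TAA")
  withr::local_seed(31)
  pad5 <- random_protein(60, c("A", "C", "G", "T"))
  g <- annotated_genome("G", paste0(pad5, cds, "CCTTGGA"), data.frame(
    locus = "cdsA", kind = "CDS", start = 61L, end = 60L + nchar(cds),
    strand = "+", phase = 0L))
  # GCT -> GCC third-position change is synonymous (both Ala)
  p <- 60L + 6L
  expect_identical(substr(g$seq, p, p), "T")
  v <- classify_effect(sub_variant(p, p, "T", "C"), g)
  expect_identical(v$effect, "synonymous")
  # substitution destroying the stop codon reads through
  ps <- 60L + nchar(cds) - 1L   # middle base of TAA
  v2 <- classify_effect(sub_variant(ps, ps, "A", "C"), g)
  expect_identical(v2$effect, "stop_loss_extension")
  # substitution destroying the start codon
  v3 <- classify_effect(sub_variant(61L, 61L, "A", "C"), g)
  expect_identical(v3$effect, "start_loss")
  # in-frame 18-bp insertion encoding ISDTND
  ins <- classify_effect(
    indel_variant(60L + 10L, 60L + 9L, "insertion", "",
                  "ATATCAGATACAAATGAT"), g)
  expect_identical(ins$effect, "inframe_indel")
  # the planted stretch indeed encodes the ISDTND hexapeptide in frame
  expect_identical(plastidcompat:::translate_cds("ATATCAGATACAAATGAT"),
                   "ISDTND")
  # 1-bp deletion shifts the frame
  fs <- classify_effect(indel_variant(60L + 8L, 60L + 8L, "deletion",
                                      substr(g$seq, 68, 68), ""), g)
  expect_identical(fs$effect, "frameshift")
})

test_that("variants outside CDS are noncoding by region rule", {
  g <- one_cds_genome("ATGGCTTAA")
  # flank5 is 7 bp; position 3 is outside any feature
  v <- classify_effect(sub_variant(3L, 3L, substr(g$seq, 3, 3), "A"), g)
  expect_identical(v$effect, "noncoding")
  g2 <- annotated_genome("G", "ACGTACGTACGTACGTACGT", data.frame(
    locus = "psbA-matK", kind = "intergenic_spacer", start = 1L,
    end = 20L, strand = "+", phase = NA))
  v2 <- classify_effect(sub_variant(5L, 5L, "A", "G"), g2)
  expect_identical(v2$effect, "noncoding")
  expect_identical(v2$region, "intergenic_spacer")
})

test_that("effect classification works on minus-strand CDS", {
  cds <- paste0("ATG", "GCTACCGATCTTGGTCGTACCAAT", "TAA")  # coding strand
  withr::local_seed(41)
  pad5 <- random_protein(60, c("A", "C", "G", "T"))
  pad3 <- random_protein(60, c("A", "C", "G", "T"))
  rc <- plastidcompat:::revcomp(cds)
  g <- annotated_genome("G", paste0(pad5, rc, pad3), data.frame(
    locus = "cdsM", kind = "CDS", start = 61L, end = 60L + nchar(rc),
    strand = "-", phase = 0L))
  # coding local pos 6 (third base of codon 2, GCT) maps to genome pos
  # end - 6 + 1; GCT -> GCC is synonymous (Ala)
  gp <- (60L + nchar(rc)) - 6L + 1L
  ref_base <- substr(g$seq, gp, gp)   # complement of T = A
  expect_identical(ref_base, "A")
  v <- classify_effect(sub_variant(gp, gp, "A", "G"), g)  # T->C coding
  expect_identical(v$effect, "synonymous")
  # coding local pos 5 (middle base of GCT): C->A gives GAT (Asp)
  gp2 <- (60L + nchar(rc)) - 5L + 1L
  expect_identical(substr(g$seq, gp2, gp2), "G")
  v2 <- classify_effect(sub_variant(gp2, gp2, "G", "T"), g)
  expect_identical(v2$effect, "nonsynonymous")
})

test_that("pattern_filter matches exhaustive per-pattern expectation", {
  accs <- c("W", "X", "Y", "Z")
  phen <- c(R = "reference", W = "incompatible_cytoplasm",
            X = "incompatible_cytoplasm", Y = "compatible_cytoplasm",
            Z = "compatible_cytoplasm")
  # one variant per presence pattern over the four non-reference accessions
  masks <- expand.grid(W = c(FALSE, TRUE), X = c(FALSE, TRUE),
                       Y = c(FALSE, TRUE), Z = c(FALSE, TRUE))
  vars <- do.call(rbind, lapply(seq_len(nrow(masks)), function(i)
    sub_variant(i * 10L, i * 10L, "A", "G")))
  pm <- structure(list(
    variants = vars,
    present = cbind(R = FALSE, as.matrix(masks)),
    phenotypes = phen), class = "presence_matrix")
  got <- pattern_filter(pm)
  want <- which(masks$W & masks$X & !masks$Y & !masks$Z)
  expect_identical(got$ref_start, vars$ref_start[want])
  # a variant present in every accession is excluded
  expect_false(160L %in% got$ref_start)
  # invariant under accession column permutation
  perm <- c("R", "Z", "X", "W", "Y")
  pm2 <- pm
  pm2$present <- pm$present[, perm]
  pm2$phenotypes <- pm$phenotypes[perm]
  expect_identical(pattern_filter(pm2), got)
  # phenotype labels are required
  pm3 <- pm
  pm3$phenotypes[] <- "reference"
  expect_error(pattern_filter(pm3), "incompatible_cytoplasm")
})

test_that("nominate_loci ranks by non-synonymous + indel burden", {
  v <- rbind(sub_variant(1L, 1L, "A", "G"),
             sub_variant(10L, 10L, "A", "G"),
             sub_variant(20L, 20L, "A", "G"),
             sub_variant(30L, 30L, "A", "G"))
  v$locus <- c("locusX", "locusX", "locusY", "spacer1-2")
  v$region <- c("CDS", "CDS", "CDS", "intergenic_spacer")
  v$effect <- c("nonsynonymous", "nonsynonymous", "synonymous",
                "noncoding")
  tab <- nominate_loci(v)
  expect_identical(tab$locus, "locusX")
  expect_identical(tab$n_nonsyn_substitutions, 2L)
  # all-noncoding input gives an empty table
  v2 <- v[4, , drop = FALSE]
  expect_identical(nrow(nominate_loci(v2)), 0L)
})

test_that("the funnel bins partition every pattern variant", {
  run <- get_screen_run(1L)
  pm <- build_presence_matrix(run$calls, run$panel$reference$id,
                              run$panel$phenotypes)
  filt <- pattern_filter(pm)
  fun <- funnel_summary(filt)
  expect_identical(fun$n_total,
                   fun$n_noncoding + fun$n_synonymous +
                     fun$n_nonsyn_substitutions + fun$n_indels)
})

test_that("an inverted segment is flagged, not effect-classified", {
  run <- get_screen_run(1L)
  ref <- run$panel$reference
  qs <- ref$seq
  seg <- substr(qs, 5000, 8441)
  qinv <- paste0(substr(qs, 1, 4999), plastidcompat:::revcomp(seg),
                 substr(qs, 8442, nchar(qs)))
  v <- align_and_call(ref, annotated_genome("INV", qinv))
  expect_identical(v$type, "inversion")
  expect_true(is.na(v$effect))
  expect_lt(abs(v$ref_start - 5000L), 30L)
  expect_lt(abs(v$ref_end - 8441L), 30L)
})

test_that("non-colinear genomes are rejected", {
  run <- get_screen_run(1L)
  ref <- run$panel$reference
  withr::local_seed(99)
  unrelated <- annotated_genome(
    "UNREL", random_protein(5000, c("A", "C", "G", "T")))
  expect_error(align_and_call(ref, unrelated), "not colinear|anchors")
})

test_that("variant tables round-trip through the TSV interchange format", {
  run <- get_screen_run(1L)
  pm <- build_presence_matrix(run$calls, run$panel$reference$id,
                              run$panel$phenotypes)
  td <- withr::local_tempdir()
  path <- file.path(td, "variants.tsv")
  write_variant_table(pm, path)
  pm2 <- read_variant_table(path, run$panel$phenotypes)
  expect_equal(pm2$variants, pm$variants)
  expect_identical(unname(pm2$present), unname(pm$present))
})
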