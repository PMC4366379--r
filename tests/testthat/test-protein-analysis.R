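test_that("derive_protein translates, rescues lost starts and reads through lost stops", {
  # minimal CDS
  g1 <- annotated_genome("t1", "AAATGTAAGG", data.frame(
    locus = "x", kind = "CDS", start = 3, end = 8, strand = "+",
    phase = 0))
  p1 <- derive_protein(g1, "x")
  expect_identical(p1$seq, "M")
  expect_identical(p1$start_mode, "annotated")
  expect_false(p1$readthrough)

  # 591-codon CDS (590 aa + stop); start disrupted, in-frame ATG at
  # codon 12 gives a 579-residue product
  withr::local_seed(53)
  cds <- paste0("ATG", plastidcompat:::random_codons(589), "TAA")
  substr(cds, 34, 36) <- "ATG"
  cds_lost <- cds
  substr(cds_lost, 1, 3) <- "CTG"
  g2 <- annotated_genome("t2", paste0("GG", cds_lost, "CCTT"), data.frame(
    locus = "x", kind = "CDS", start = 3, end = 2 + nchar(cds_lost),
    strand = "+", phase = 0))
  p2 <- derive_protein(g2, "x")
  expect_identical(p2$start_mode, "alternative_downstream")
  expect_identical(nchar(p2$seq), 579L)
  expect_lt(nchar(p2$seq),
            nchar(derive_protein(annotated_genome(
              "t2b", paste0("GG", cds, "CCTT"), g2$features), "x")$seq))

  # no in-frame ATG in the scan window
  g3 <- annotated_genome("t3", paste0("GG", cds_lost, "CC"), g2$features)
  expect_error(derive_protein(g3, "x", scan_codons = 5L),
               "no alternative start")

  # stop disrupted: translation extends into downstream genomic sequence
  cds_rt <- cds
  substr(cds_rt, nchar(cds) - 2, nchar(cds)) <- "CAA"
  g4 <- annotated_genome("t4", paste0("GG", cds_rt, "GCAGCTTAAGG"),
                         data.frame(locus = "x", kind = "CDS", start = 3,
                                    end = 2 + nchar(cds_rt), strand = "+",
                                    phase = 0))
  p4 <- derive_protein(g4, "x")
  expect_true(p4$readthrough)
  expect_identical(nchar(p4$seq), 590L + 3L)  # Q + A + A before TAA
})

test_that("align_proteins resolves substitutions, deletions and shared insertions", {
  s <- c(A = "MKTWLSDHQR", B = "MKTWLSEHQR")
  al <- align_proteins(s)
  v <- variable_position_table(al)
  expect_identical(nrow(v), 1L)
  expect_identical(v$kind, "replacement")
  # identical sequences: zero variable columns
  v0 <- variable_position_table(align_proteins(c(A = "MKTWLSDHQR",
                                                 B = "MKTWLSDHQR")))
  expect_identical(nrow(v0), 0L)
  # a planted contiguous 6-residue deletion gives one 6-column gap block
  withr::local_seed(61)
  base <- random_protein(60, strsplit("ADFGHIKLNPQRSTVWY", "")[[1]])
  delled <- paste0(substr(base, 1, 24), substr(base, 31, 60))
  v6 <- variable_position_table(align_proteins(c(REF = base, D = delled)))
  expect_identical(nrow(v6), 1L)
  expect_identical(v6$kind, "deletion")
  expect_identical(v6$n_residues, 6L)
  # empty sequences are rejected
  expect_error(align_proteins(c(A = "MKT", B = "")), "empty")
})

test_that("the reconstructed accD alignment reproduces its variation table row-for-row", {
  t1 <- accd_variation_table()
  vpt <- variable_position_table(accd_alignment())
  expect_equal(as.data.frame(vpt), as.data.frame(t1),
               ignore_attr = TRUE)
  s <- variation_summary(vpt)
  expect_identical(attr(vpt, "alignment_length"), 610L)
  expect_identical(s$n_variable_positions, 19L)
  expect_identical(s$n_indel_columns, 80L)
  # reference product is 590 aa (610 columns minus 20 insertion-only
  # columns); the read-through JI1794 product is 8 aa longer plus its
  # 3-residue insertion
  seqs <- alignment_sequences(accd_alignment())
  expect_identical(nchar(seqs[["WL1238"]]), 590L)
  expect_identical(nchar(seqs[["JI1794"]]), 590L + 3L + 8L)
})

test_that("exclusive accD differences match the published summary", {
  t1 <- accd_variation_table()
  ex <- exclusive_differences(t1, c("VIR320", "L100"))
  s <- variation_summary(ex)
  expect_identical(s$n_replaced_residues, 7L)
  expect_identical(sort(s$deletion_sizes, decreasing = TRUE),
                   c(8L, 3L, 1L))
  # disjointness with the complementary target
  ex2 <- exclusive_differences(t1, c("JI1794", "721"))
  expect_identical(intersect(rownames(ex), rownames(ex2)), character(0))
  expect_error(exclusive_differences(t1, c("VIR320"), c("VIR320", "721")),
               "overlap")
})

test_that("the Bccp3 table has nine variable positions, no indels, four exclusives in the biotinyl domain", {
  t2 <- bccp3_variation_table()
  vpt <- variable_position_table(bccp3_alignment())
  expect_equal(as.data.frame(vpt), as.data.frame(t2),
               ignore_attr = TRUE)
  s <- variation_summary(vpt)
  expect_identical(attr(vpt, "alignment_length"), 290L)
  expect_identical(s$n_variable_positions, 9L)
  expect_identical(s$n_indel_columns, 0L)
  ex <- exclusive_differences(t2, c("VIR320", "L100"))
  expect_identical(ex$start, c(211L, 252L, 254L, 279L))
  dom <- attr(t2, "biotinyl_domain")
  expect_true(all(ex$start >= dom[1] & ex$end <= dom[2]))
  # single-sequence alignment: empty table
  one <- matrix(strsplit("MKT", "")[[1]], nrow = 1,
                dimnames = list("X", NULL))
  expect_identical(nrow(variable_position_table(one)), 0L)
})

test_that("de novo progressive alignment of the accD products recovers the tabulated structure", {
  seqs <- alignment_sequences(accd_alignment())
  al <- align_proteins(as.list(seqs))
  # degap identity: alignment loses no residues
  expect_identical(alignment_sequences(al)[names(seqs)], seqs)
  s <- variation_summary(variable_position_table(al))
  expect_identical(s$n_variable_positions, 19L)
  expect_identical(s$n_indel_columns, 80L)
  expect_identical(ncol(al), 610L)
})

test_that("find_tandem_repeats equals the exhaustive oracle", {
  withr::local_seed(71)
  for (i in 1:40) {
    n <- sample(10:30, 1)
    s <- random_protein(n)            # 4-letter alphabet
    rng <- c(1L, n %/% 2L)
    expect_identical(find_tandem_repeats(s, rng), tandem_oracle(s, rng),
                     info = s)
  }
  # repeat-free string
  expect_identical(nrow(find_tandem_repeats("ABCDEFGHIJKLMNOPQR")), 0L)
})

test_that("the duplicated ISDTND hexapeptide and poly-E runs are annotated as published", {
  seqs <- alignment_sequences(accd_alignment())
  tr <- find_tandem_repeats(seqs[["WL1238"]], c(6L, 6L))
  isdtnd <- tr[tr$unit == "ISDTND", , drop = FALSE]
  expect_identical(isdtnd$copies, 2L)
  expect_identical(isdtnd$start, 124L)
  # 721 and L100 carry a single copy at the duplication region: no
  # ISDTND tandem array there
  tr721 <- find_tandem_repeats(seqs[["721"]], c(6L, 6L))
  expect_false(any(tr721$unit == "ISDTND" & tr721$start < 150L))
  # poly-E: three residues in WL1238, JI1794 and VIR320; four in L100;
  # six in 721
  polyE <- vapply(seqs, function(x) poly_run(x, "E")$length, integer(1))
  expect_identical(polyE[["WL1238"]], 3L)
  expect_identical(polyE[["JI1794"]], 3L)
  expect_identical(polyE[["VIR320"]], 3L)
  expect_identical(polyE[["L100"]], 4L)
  expect_identical(polyE[["721"]], 6L)
  # absent residue: zero-length run with empty span
  pr <- poly_run("ACDF", "W")
  expect_identical(pr$length, 0L)
  expect_identical(pr$start, integer(0))
  # random strings agree with a linear-scan oracle
  withr::local_seed(73)
  for (i in 1:20) {
    s <- random_protein(40, c("A", "E", "G"))
    r <- rle(strsplit(s, "")[[1]])
    want <- suppressWarnings(max(0L, r$lengths[r$values == "E"]))
    expect_identical(poly_run(s, "E")$length, as.integer(want))
  }
})

test_that("the zinc-finger motif scan finds the CX2CX15CX2C span containing position 240", {
  seqs <- alignment_sequences(accd_alignment())
  zf <- scan_zinc_finger(seqs[["WL1238"]])
  expect_identical(nrow(zf), 1L)
  # map the sequence span to alignment columns: 9 insertion-only columns
  # (141-143, 175-180) precede the motif in the reference row
  expect_identical(zf$start + 9L, 228L)
  expect_identical(zf$end + 9L, 250L)
  expect_true(zf$start + 9L <= 240L && 240L <= zf$end + 9L)
  # cysteine-free sequence: no matches
  expect_identical(nrow(scan_zinc_finger(strrep("AD", 30))), 0L)
  # constructed sequence with exactly one conforming spacing
  probe <- paste0("AA", "C", "DD", "C", strrep("G", 15), "C", "HH", "C",
                  "AA")
  expect_identical(scan_zinc_finger(probe),
                   data.frame(start = 3L, end = 25L))
})
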