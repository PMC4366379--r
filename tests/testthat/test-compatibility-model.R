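test_that("cytoplasmic determinant flags derive from the accD profile", {
  cyt <- cytoplasm_genotype_from_features(accd_variation_table())
  g <- function(a) cyt[cyt$accession == a, ]
  expect_true(g("VIR320")$cyt_primary)
  expect_true(g("VIR320")$cyt_secondary)
  expect_true(g("L100")$cyt_primary)
  expect_false(g("L100")$cyt_secondary)
  expect_false(g("721")$cyt_primary)
  expect_false(g("721")$cyt_secondary)
  expect_false(g("WL1238")$cyt_primary)
  expect_true(g("WL1238")$cyt_secondary)
  # the alternative poly-E predicate gives the same secondary assignment
  cyt2 <- cytoplasm_genotype_from_features(accd_variation_table(),
                                           secondary = "poly_e")
  expect_identical(cyt2$cyt_secondary, cyt$cyt_secondary)
  # a table that does not cover the duplication region is rejected
  short <- bccp3_variation_table()
  expect_error(cytoplasm_genotype_from_features(short,
                                                dup_region = c(400L, 411L)),
               "duplication region")
})

test_that("the nuclear primary binding site follows the Bccp3 exclusive set", {
  nuc <- nuclear_genotype_from_features(bccp3_variation_table())
  expect_identical(nuc$nuc_bind_primary[match(
    c("VIR320", "L100", "WL1238", "JI1794", "721"), nuc$accession)],
    c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("predict_cross reproduces every unambiguous published cross", {
  panel <- pea_determinant_panel()
  obs <- pea_cross_outcomes()
  expect_identical(nrow(obs), 15L)
  for (i in seq_len(nrow(obs))) {
    cyt <- panel[panel$accession == obs$cytoplasm_donor[i], ]
    nuc <- panel[panel$accession == obs$nuclear_donor[i], ]
    expect_identical(predict_cross(cyt, nuc), obs$outcome[i],
                     info = paste(obs$cytoplasm_donor[i], "x",
                                  obs$nuclear_donor[i]))
  }
  # unknown flags demand resolution
  cyt <- panel[1, ]; cyt$cyt_secondary <- NA
  expect_error(predict_cross(cyt, panel[2, ]), "unknown")
})

test_that("self-compatibility and primary masking hold across the flag space", {
  states <- expand.grid(P = c(FALSE, TRUE), S = c(FALSE, TRUE),
                        bp = c(FALSE, TRUE), bs = c(FALSE, TRUE))
  gt <- function(i) determinant_genotype("x", states$P[i], states$S[i],
                                         states$bp[i], states$bs[i])
  # every accession of the pea panel is self-compatible
  panel <- pea_determinant_panel()
  for (i in seq_len(nrow(panel)))
    expect_identical(predict_cross(panel[i, ], panel[i, ]), "compatible")
  # masking: when cyt_primary is TRUE, flipping cyt_secondary never
  # changes any prediction (quantified over all genotype pairs)
  for (i in seq_len(nrow(states))) {
    if (!states$P[i]) next
    flip <- gt(i); flip$cyt_secondary <- !flip$cyt_secondary
    for (j in seq_len(nrow(states)))
      expect_identical(predict_cross(gt(i), gt(j)),
                       predict_cross(flip, gt(j)))
  }
})

test_that("forward_panel closes the rule over all ordered pairs", {
  panel <- pea_determinant_panel()
  fp <- forward_panel(panel)
  expect_identical(nrow(fp), 25L)
  selfs <- fp[fp$cytoplasm_donor == fp$nuclear_donor, ]
  expect_true(all(selfs$outcome == "compatible"))
  # single all-false accession: one compatible self
  g0 <- determinant_genotype("solo", FALSE, FALSE, FALSE, FALSE)
  expect_identical(forward_panel(g0),
                   data.frame(cytoplasm_donor = "solo",
                              nuclear_donor = "solo",
                              outcome = "compatible",
                              stringsAsFactors = FALSE))
})

test_that("infer_states recovers the published determinant structure", {
  inf <- infer_states(pea_cross_outcomes(include_selfs = TRUE))
  expect_true(inf$consistent)
  expect_identical(inf$n_solutions, 4L)
  id <- inf$identifiability
  row <- function(a) id[id$accession == a, ]
  # fixed flags
  expect_equal(row("WL1238")[, -1],
               data.frame(cyt_primary = FALSE, cyt_secondary = TRUE,
                          nuc_bind_primary = FALSE,
                          nuc_bind_secondary = TRUE),
               ignore_attr = TRUE)
  expect_true(row("VIR320")$cyt_primary)
  expect_true(row("L100")$cyt_primary)
  expect_true(row("VIR320")$nuc_bind_primary)
  expect_true(row("L100")$nuc_bind_primary)
  expect_false(row("L100")$nuc_bind_secondary)
  expect_false(row("721")$cyt_primary)
  expect_false(row("721")$cyt_secondary)
  expect_identical(row("JI1794")[, -1], row("WL1238")[, -1],
                   ignore_attr = TRUE)
  # cyt_secondary of the primary-carrying accessions is masked, hence free
  expect_true(is.na(row("VIR320")$cyt_secondary))
  expect_true(is.na(row("L100")$cyt_secondary))
  # the curated truth panel is among the solutions
  truth <- pea_determinant_panel()
  hit <- vapply(inf$solutions, function(s) {
    s2 <- s[match(truth$accession, s$accession), ]
    all(s2[, -1] == truth[, -1])
  }, logical(1))
  expect_true(any(hit))
})

test_that("an empty outcome list leaves every assignment consistent", {
  inf <- infer_states(data.frame(cytoplasm_donor = character(),
                                 nuclear_donor = character(),
                                 outcome = character()),
                      accessions = c("a", "b"))
  expect_true(inf$consistent)
  expect_identical(inf$n_solutions, 16^2)
  expect_true(all(is.na(as.matrix(inf$identifiability[, -1]))))
})

test_that("inconsistent observations yield a minimal conflicting subset", {
  out <- data.frame(
    cytoplasm_donor = c("a", "a", "b"),
    nuclear_donor = c("b", "b", "a"),
    outcome = c("compatible", "incompatible", "compatible"),
    stringsAsFactors = FALSE)
  inf <- infer_states(out)
  expect_false(inf$consistent)
  expect_identical(inf$n_solutions, 0L)
  # the two contradictory a x b records suffice as a conflict
  expect_identical(nrow(inf$conflicts), 2L)
  expect_true(all(inf$conflicts$cytoplasm_donor == "a"))
})

test_that("forward-simulated panels are recovered flag-for-flag", {
  for (i in 1:25) {
    sim <- sim_cross_panel(n_accessions = 4L + (i %% 3L), seed = 700L + i)
    inf <- infer_states(sim$outcomes)
    expect_true(inf$consistent)
    hit <- vapply(inf$solutions, function(s)
      all(s[, -1] == sim$genotypes[, -1]), logical(1))
    expect_true(any(hit))
    id <- as.matrix(inf$identifiability[, -1])
    tv <- as.matrix(sim$genotypes[, -1])
    fixed <- !is.na(id)
    expect_true(all(id[fixed] == tv[fixed]))
  }
})
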