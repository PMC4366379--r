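test_that("recombinant_count applies the Haldane-Waddington correction", {
  ril <- pea_ril_table()
  # identical columns: zero recombinants throughout
  rc0 <- recombinant_count(ril, "Bccp3", "Scs1")
  expect_identical(rc0$n_recombinant, 0L)
  expect_identical(rc0$R, 0)
  expect_identical(rc0$r, 0)
  expect_identical(rc0$cM, 0)
  # algebraic identity r = R / (2 - 2R)
  tbl <- sim_ril_population(
    n_lines = 0, loci = c("a", "b"), r = 0,
    patterns = c(AB = 1L, AA = 9L))$table
  rc <- recombinant_count(tbl, "a", "b")
  expect_identical(rc$R, 0.1)
  expect_equal(rc$r, 0.1 / (2 - 2 * 0.1))
  expect_equal(rc$r, 0.05555556, tolerance = 1e-6)
  # symmetry
  rc_ab <- recombinant_count(ril, "PhlC", "AJ832139")
  rc_ba <- recombinant_count(ril, "AJ832139", "PhlC")
  expect_identical(rc_ab, rc_ba)
  # the correction shrinks: r <= R on (0, 0.5), with r -> 0.5 at R = 0.5
  R <- seq(0.01, 0.49, by = 0.02)
  r <- R / (2 - 2 * R)
  expect_true(all(r <= R))
  expect_equal(0.5 / (2 - 2 * 0.5), 0.5)
  # missing entries are excluded pairwise
  ril2 <- ril
  ril2[1:5, "PhlC"] <- NA
  expect_identical(recombinant_count(ril2, "PhlC", "Bccp3")$n_scored, 83L)
  ril3 <- ril
  ril3[, "PhlC"] <- NA
  expect_error(recombinant_count(ril3, "PhlC", "Bccp3"),
               "no commonly scored")
})

test_that("the 88-line population reproduces the published crossover counts", {
  ril <- pea_ril_table()
  expect_identical(nrow(ril), 88L)
  expect_identical(recombinant_count(ril, "PhlC", "AJ832139")$n_recombinant,
                   5L)
  expect_identical(recombinant_count(ril, "Bccp3", "PhlC")$n_recombinant,
                   2L)
  expect_identical(recombinant_count(ril, "Bccp3",
                                     "AJ832139")$n_recombinant, 3L)
})

test_that("three-point ordering places the middle locus and flags ties", {
  ril <- pea_ril_table()
  o <- order_three(ril, "PhlC", "Bccp3", "AJ832139")
  expect_identical(o$order, c("PhlC", "Bccp3", "AJ832139"))
  expect_identical(o$double_recombinants, 0L)
  expect_false(o$ambiguous)
  # all columns identical: ambiguous, not an exception
  same <- sim_ril_population(0, c("a", "b", "c"), r = c(0, 0),
                             patterns = c(AAA = 5L, BBB = 5L))$table
  oa <- order_three(same, "a", "b", "c")
  expect_true(oa$ambiguous)
  # random tables agree with brute-force evaluation of all middles
  withr::local_seed(83)
  for (i in 1:15) {
    sim <- sim_ril_population(50, c("a", "b", "c"),
                              r = runif(2, 0.02, 0.3), seed = i)
    got <- order_three(sim$table, "a", "b", "c")
    counts <- vapply(c("a", "b", "c"), function(mid) {
      fl <- setdiff(c("a", "b", "c"), mid)
      sum(sim$table[, mid] != sim$table[, fl[1]] &
            sim$table[, mid] != sim$table[, fl[2]])
    }, integer(1))
    expect_identical(unname(got$double_recombinants),
                     unname(min(counts)))
    if (!got$ambiguous)
      expect_identical(got$order[2], names(which.min(counts)))
  }
})

test_that("cosegregation counts marker-phenotype agreement", {
  ril <- pea_ril_table()
  scs1 <- stats::setNames(ril[, "Scs1"], rownames(ril))
  cs <- cosegregation(ril, "Bccp3", scs1)
  expect_identical(cs, list(n_match = 88L, n_scored = 88L))
  # one planted discordance
  scs1_d <- scs1
  scs1_d[40] <- if (scs1_d[40] == "A") "B" else "A"
  expect_identical(cosegregation(ril, "Bccp3", scs1_d)$n_match, 87L)
  # disjoint line sets are an error
  expect_error(cosegregation(ril, "Bccp3",
                             stats::setNames("A", "NOSUCH")),
               "commonly scored")
})

test_that("simulated RIL populations recover the per-meiosis r", {
  # r = 0 everywhere: no recombinant lines
  sim0 <- sim_ril_population(200, c("a", "b"), r = 0, seed = 4L)
  expect_identical(recombinant_count(sim0$table, "a", "b")$n_recombinant,
                   0L)
  expect_error(sim_ril_population(10, c("a", "b"), r = 0.6),
               "0.5")
  # n = 10,000 at r0 = 0.05: estimate within 3 binomial SE
  r0 <- 0.05
  sim <- sim_ril_population(10000, c("a", "b"), r = r0, seed = 11L)
  rc <- recombinant_count(sim$table, "a", "b")
  se_R <- sqrt(rc$R * (1 - rc$R) / rc$n_scored)
  se_r <- se_R * 2 / (2 - 2 * rc$R)^2     # delta method
  expect_lte(abs(rc$r - r0), 3 * se_r)
  # determinism
  sim2 <- sim_ril_population(10000, c("a", "b"), r = r0, seed = 11L)
  expect_identical(sim2$table, sim$table)
})

test_that("RIL tables round-trip through TSV", {
  ril <- pea_ril_table()
  ril[3, "PhlC"] <- NA
  td <- withr::local_tempdir()
  p <- file.path(td, "ril.tsv")
  write_ril_table(ril, p)
  back <- read_ril_table(p)
  expect_identical(unclass(back), unclass(ril))
})
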