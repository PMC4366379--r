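#' Determinant genotypes
#'
#' A determinant genotype records, per accession, four boolean flags of
#' the primary/secondary determinant model of plastid-nuclear
#' compatibility: whether the plastid carboxyltransferase beta-subunit
#' product carries the primary determinant (`cyt_primary`) and/or the
#' secondary determinant (`cyt_secondary`), and whether the
#' nuclear-encoded counterpart carries the binding site fitted to each
#' (`nuc_bind_primary`, `nuc_bind_secondary`).
#'
#' @param accession Label(s).
#' @param cyt_primary,cyt_secondary,nuc_bind_primary,nuc_bind_secondary
#'   Logical vectors recycled to `length(accession)`.
#' @return `data.frame` with one row per accession.
#' @export
determinant_genotype <- function(accession, cyt_primary, cyt_secondary,
                                 nuc_bind_primary, nuc_bind_secondary) {
  data.frame(accession = accession,
             cyt_primary = as.logical(cyt_primary),
             cyt_secondary = as.logical(cyt_secondary),
             nuc_bind_primary = as.logical(nuc_bind_primary),
             nuc_bind_secondary = as.logical(nuc_bind_secondary),
             stringsAsFactors = FALSE)
}

#' Derive cytoplasmic determinant flags from a variation-table profile
#'
#' The primary determinant is operationalised as carrying the complete
#' exclusive change set of the incompatible cytoplasms (every row of
#' [exclusive_differences()] for the target set). The secondary
#' determinant is the tandem duplication of the ISDTND hexapeptide at the
#' duplication region (an accession carries it unless it carries a
#' deletion row overlapping that region); alternatively
#' (`secondary = "poly_e"`) a poly-E run of at most 3 residues in the
#' derived protein.
#'
#' @param table A [variable_position_table()] for the plastid
#'   carboxyltransferase beta subunit.
#' @param primary_target Accession set whose exclusive change set defines
#'   the primary determinant.
#' @param dup_region Alignment columns of the duplicated hexapeptide.
#' @param secondary `"isdtnd_duplication"` (default) or `"poly_e"`.
#' @param max_poly_e Poly-E run length at or below which the secondary
#'   determinant is scored present (only for `secondary = "poly_e"`).
#' @return `data.frame` with columns `accession`, `cyt_primary`,
#'   `cyt_secondary` covering the reference and all table accessions.
#' @export
cytoplasm_genotype_from_features <- function(table,
                                             primary_target =
                                               c("VIR320", "L100"),
                                             dup_region = c(124L, 135L),
                                             secondary =
                                               "isdtnd_duplication",
                                             max_poly_e = 3L) {
  stopifnot(inherits(table, "variable_position_table"))
  secondary <- match.arg(secondary, c("isdtnd_duplication", "poly_e"))
  L <- attr(table, "alignment_length")
  if (is.null(L) || L < dup_region[2])
    stop("profile does not cover the duplication region ",
         dup_region[1], "-", dup_region[2])
  accs <- c(attr(table, "reference"), attr(table, "acc_set"))
  occ <- strsplit(table$accessions, ",", fixed = TRUE)
  excl <- exclusive_differences(table, primary_target)
  cyt_primary <- vapply(accs, function(a) {
    if (a == attr(table, "reference")) return(FALSE)
    nrow(excl) > 0L &&
      all(vapply(strsplit(excl$accessions, ",", fixed = TRUE),
                 function(o) a %in% o, logical(1)))
  }, logical(1))
  if (secondary == "isdtnd_duplication") {
    del_rows <- which(table$kind %in% c("deletion", "terminal_absence") &
                        table$start <= dup_region[2] &
                        table$end >= dup_region[1])
    cyt_secondary <- vapply(accs, function(a) {
      if (a == attr(table, "reference")) return(TRUE)
      !any(vapply(occ[del_rows], function(o) a %in% o, logical(1)))
    }, logical(1))
  } else {
    aln <- reconstruct_alignment(table)
    seqs <- alignment_sequences(aln)
    cyt_secondary <- vapply(accs, function(a)
      poly_run(seqs[[a]], "E")$length <= max_poly_e, logical(1))
  }
  data.frame(accession = accs, cyt_primary = unname(cyt_primary),
             cyt_secondary = unname(cyt_secondary),
             stringsAsFactors = FALSE)
}

#' Derive the primary-determinant binding-site flag from the nuclear
#' counterpart's variation table
#'
#' An accession's nuclear product carries the binding site fitted to the
#' primary determinant iff it carries the complete exclusive substitution
#' set of the target accessions (the biotinyl-domain changes).
#'
#' @inheritParams cytoplasm_genotype_from_features
#' @return `data.frame` with columns `accession`, `nuc_bind_primary`.
#' @export
nuclear_genotype_from_features <- function(table,
                                           primary_target =
                                             c("VIR320", "L100")) {
  stopifnot(inherits(table, "variable_position_table"))
  accs <- c(attr(table, "reference"), attr(table, "acc_set"))
  excl <- exclusive_differences(table, primary_target)
  flag <- vapply(accs, function(a) {
    if (a == attr(table, "reference")) return(FALSE)
    nrow(excl) > 0L &&
      all(vapply(strsplit(excl$accessions, ",", fixed = TRUE),
                 function(o) a %in% o, logical(1)))
  }, logical(1))
  data.frame(accession = accs, nuc_bind_primary = unname(flag),
             stringsAsFactors = FALSE)
}

#' Determinant genotype panel of the five pea accessions
#'
#' Combines feature-derived flags (cytoplasmic flags from the
#' carboxyltransferase beta-subunit variation table; the
#' primary-determinant binding site from the biotin carboxyl carrier
#' protein table) with the curated secondary binding-site assignment (the
#' hypothesised second nuclear locus, possibly the holocarboxylase
#' synthetase gene; it is deliberately never derived from the BCCP
#' sequence, which cannot encode both binding sites at once).
#'
#' @return A determinant-genotype `data.frame`, one row per accession.
#' @export
pea_determinant_panel <- function() {
  cyt <- cytoplasm_genotype_from_features(accd_variation_table())
  nuc <- nuclear_genotype_from_features(bccp3_variation_table())
  bs <- c(WL1238 = TRUE, JI1794 = TRUE, `721` = FALSE, L100 = FALSE,
          VIR320 = TRUE)
  g <- merge(cyt, nuc, by = "accession", sort = FALSE)
  g$nuc_bind_secondary <- unname(bs[g$accession])
  g <- g[match(pea_accessions(), g$accession), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Predict the outcome of a directed cross
#'
#' Rule order of the primary/secondary determinant model: (1) if the
#' cytoplasm donor's plastid product carries the primary determinant, the
#' cross is compatible iff the nuclear donor carries the fitted primary
#' binding site, else incompatible; (2) otherwise, if it carries the
#' secondary determinant, compatible iff the fitted secondary binding
#' site is present, else incompatible; (3) with neither determinant, the
#' cross is compatible, except that a vacant secondary binding site in
#' the nuclear product makes it partially compatible (decreased pollen
#' fertility rather than lethality).
#'
#' @param cyt One-row determinant genotype of the cytoplasm (maternal)
#'   donor.
#' @param nuc One-row determinant genotype of the nuclear donor.
#' @return One of `"compatible"`, `"partial"`, `"incompatible"`.
#' @export
predict_cross <- function(cyt, nuc) {
  flags <- c(cyt$cyt_primary, cyt$cyt_secondary,
             nuc$nuc_bind_primary, nuc$nuc_bind_secondary)
  if (anyNA(flags))
    stop("unknown determinant flag; resolve all flags before prediction")
  rule_outcome(cyt$cyt_primary, cyt$cyt_secondary,
               nuc$nuc_bind_primary, nuc$nuc_bind_secondary)
}

rule_outcome <- function(P, S, bp, bs) {
  if (P) {
    if (bp) "compatible" else "incompatible"
  } else if (S) {
    if (bs) "compatible" else "incompatible"
  } else {
    if (bs) "partial" else "compatible"
  }
}

#' Deterministic closure of the rule engine over a genotype panel
#'
#' @param genotypes Determinant-genotype `data.frame` (one row per
#'   accession, all flags resolved).
#' @return `data.frame` of all n^2 directed crosses (including selfs)
#'   with columns `cytoplasm_donor`, `nuclear_donor`, `outcome`.
#' @export
forward_panel <- function(genotypes) {
  n <- nrow(genotypes)
  grid <- expand.grid(ci = seq_len(n), ni = seq_len(n))
  out <- vapply(seq_len(nrow(grid)), function(k)
    predict_cross(genotypes[grid$ci[k], ], genotypes[grid$ni[k], ]),
    character(1))
  data.frame(cytoplasm_donor = genotypes$accession[grid$ci],
             nuclear_donor = genotypes$accession[grid$ni],
             outcome = out, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## State inference by exhaustive constraint satisfaction

# Flag pairs are packed as integers 0..3: value = P + 2*S (cytoplasm side)
# or bp + 2*bs (nuclear side).
# 4x4 outcome table: rows = cyt pair value, cols = nuc pair value.
rule_table <- function() {
  m <- matrix("", 4L, 4L)
  for (c. in 0:3) for (n. in 0:3) {
    P <- c. %% 2L == 1L; S <- c. %/% 2L == 1L
    bp <- n. %% 2L == 1L; bs <- n. %/% 2L == 1L
    m[c. + 1L, n. + 1L] <- rule_outcome(P, S, bp, bs)
  }
  m
}

#' Infer determinant states from observed cross outcomes
#'
#' Exhaustive search over the 16 flag combinations per accession,
#' organised as a constraint-satisfaction problem: each observed cross
#' constrains the (cyt_primary, cyt_secondary) pair of the cytoplasm
#' donor jointly with the (nuc_bind_primary, nuc_bind_secondary) pair of
#' the nuclear donor. Domains are pruned by arc consistency, then all
#' satisfying joint assignments are enumerated. Per-flag identifiability
#' is reported: a flag is `fixed` when it takes the same value in every
#' solution, `free` otherwise.
#'
#' @param outcomes `data.frame` with columns `cytoplasm_donor`,
#'   `nuclear_donor`, `outcome`.
#' @param accessions Optional accession universe; defaults to all
#'   accessions named in `outcomes`.
#' @return Object of class `compat_inference`: list with `consistent`
#'   (logical), `n_solutions`, `solutions` (list of determinant-genotype
#'   `data.frame`s; `NULL` when no outcome constrains anything),
#'   `identifiability` (`data.frame` accession x flag with the fixed value
#'   or `NA` when free), and, when inconsistent, `conflicts` (a minimal
#'   conflicting outcome subset).
#' @export
infer_states <- function(outcomes, accessions = NULL) {
  if (is.null(accessions))
    accessions <- unique(c(outcomes$cytoplasm_donor,
                           outcomes$nuclear_donor))
  n <- length(accessions)
  if (n == 0L || nrow(outcomes) == 0L) {
    ident <- data.frame(accession = accessions,
                        cyt_primary = NA, cyt_secondary = NA,
                        nuc_bind_primary = NA, nuc_bind_secondary = NA)
    return(structure(list(consistent = TRUE, n_solutions = 16^n,
                          solutions = NULL, identifiability = ident),
                     class = "compat_inference"))
  }
  bad <- !outcomes$outcome %in% c("compatible", "partial", "incompatible")
  if (any(bad)) stop("unknown outcome class: ",
                     paste(unique(outcomes$outcome[bad]), collapse = ", "))
  rt <- rule_table()
  # variables: C_1..C_n then B_1..B_n, domains subsets of 0:3
  doms <- rep(list(0:3), 2L * n)
  cons <- lapply(seq_len(nrow(outcomes)), function(k) {
    ci <- match(outcomes$cytoplasm_donor[k], accessions)
    ni <- match(outcomes$nuclear_donor[k], accessions)
    if (is.na(ci) || is.na(ni))
      stop("outcome names accession outside the accession universe")
    allowed <- rt == outcomes$outcome[k]
    list(cvar = ci, bvar = n + ni, allowed = allowed, row = k)
  })
  res <- csp_solve(doms, cons)
  if (!res$consistent) {
    conflict <- minimal_conflict(outcomes, accessions)
    ident <- data.frame(accession = accessions,
                        cyt_primary = NA, cyt_secondary = NA,
                        nuc_bind_primary = NA, nuc_bind_secondary = NA)
    return(structure(list(consistent = FALSE, n_solutions = 0L,
                          solutions = list(), identifiability = ident,
                          conflicts = conflict),
                     class = "compat_inference"))
  }
  sols <- res$solutions   # matrix: one row per solution, 2n columns
  to_panel <- function(i) {
    determinant_genotype(
      accessions,
      cyt_primary = sols[i, seq_len(n)] %% 2L == 1L,
      cyt_secondary = sols[i, seq_len(n)] %/% 2L == 1L,
      nuc_bind_primary = sols[i, n + seq_len(n)] %% 2L == 1L,
      nuc_bind_secondary = sols[i, n + seq_len(n)] %/% 2L == 1L)
  }
  fixed_val <- function(col) {
    u <- unique(col)
    if (length(u) == 1L) u else NA
  }
  cvals <- sols[, seq_len(n), drop = FALSE]
  bvals <- sols[, n + seq_len(n), drop = FALSE]
  ident <- data.frame(
    accession = accessions,
    cyt_primary = vapply(seq_len(n), function(j)
      fixed_val(cvals[, j] %% 2L == 1L), NA),
    cyt_secondary = vapply(seq_len(n), function(j)
      fixed_val(cvals[, j] %/% 2L == 1L), NA),
    nuc_bind_primary = vapply(seq_len(n), function(j)
      fixed_val(bvals[, j] %% 2L == 1L), NA),
    nuc_bind_secondary = vapply(seq_len(n), function(j)
      fixed_val(bvals[, j] %/% 2L == 1L), NA),
    stringsAsFactors = FALSE)
  structure(list(consistent = TRUE, n_solutions = nrow(sols),
                 solutions = lapply(seq_len(nrow(sols)), to_panel),
                 identifiability = ident),
            class = "compat_inference")
}

#' @export
print.compat_inference <- function(x, ...) {
  cat("<compat_inference> ",
      if (x$consistent) paste0(x$n_solutions, " consistent assignment(s)")
      else "INCONSISTENT", "\n", sep = "")
  print(x$identifiability)
  invisible(x)
}

# AC-3 style pruning followed by exhaustive backtracking enumeration.
csp_solve <- function(doms, cons, find_all = TRUE) {
  repeat {
    changed <- FALSE
    for (con in cons) {
      dc <- doms[[con$cvar]]; db <- doms[[con$bvar]]
      keep_c <- vapply(dc, function(v)
        any(con$allowed[v + 1L, db + 1L]), logical(1))
      keep_b <- vapply(db, function(v)
        any(con$allowed[dc + 1L, v + 1L]), logical(1))
      if (!all(keep_c)) { doms[[con$cvar]] <- dc[keep_c]; changed <- TRUE }
      if (!all(keep_b)) { doms[[con$bvar]] <- db[keep_b]; changed <- TRUE }
      if (!length(doms[[con$cvar]]) || !length(doms[[con$bvar]]))
        return(list(consistent = FALSE, solutions = NULL))
    }
    if (!changed) break
  }
  nv <- length(doms)
  # constraints indexed by variable for incremental checking
  by_var <- vector("list", nv)
  for (ci in seq_along(cons)) {
    con <- cons[[ci]]
    by_var[[max(con$cvar, con$bvar)]] <-
      c(by_var[[max(con$cvar, con$bvar)]], list(con))
  }
  sols <- list()
  assign_ <- integer(nv)
  recurse <- function(v) {
    if (v > nv) {
      sols[[length(sols) + 1L]] <<- assign_
      return(!find_all)   # TRUE = stop search
    }
    for (val in doms[[v]]) {
      assign_[v] <<- val
      ok <- TRUE
      for (con in by_var[[v]]) {
        cv <- assign_[con$cvar]; bv <- assign_[con$bvar]
        if (!con$allowed[cv + 1L, bv + 1L]) { ok <- FALSE; break }
      }
      if (ok && recurse(v + 1L)) return(TRUE)
    }
    FALSE
  }
  recurse(1L)
  if (!length(sols)) return(list(consistent = FALSE, solutions = NULL))
  list(consistent = TRUE, solutions = do.call(rbind, sols))
}

infer_states_consistent <- function(outcomes, accessions) {
  n <- length(accessions)
  rt <- rule_table()
  doms <- rep(list(0:3), 2L * n)
  cons <- lapply(seq_len(nrow(outcomes)), function(k) {
    ci <- match(outcomes$cytoplasm_donor[k], accessions)
    ni <- match(outcomes$nuclear_donor[k], accessions)
    list(cvar = ci, bvar = n + ni, allowed = rt == outcomes$outcome[k])
  })
  csp_solve(doms, cons, find_all = FALSE)$consistent
}

# Deletion-based minimal conflicting outcome subset.
minimal_conflict <- function(outcomes, accessions) {
  keep <- seq_len(nrow(outcomes))
  for (i in seq_len(nrow(outcomes))) {
    trial <- setdiff(keep, i)
    if (!length(trial)) next
    if (!infer_states_consistent(outcomes[trial, , drop = FALSE],
                                 accessions)) {
      keep <- trial
    }
  }
  outcomes[keep, , drop = FALSE]
}

#' Simulate a cross-outcome panel from known determinant genotypes
#'
#' Samples a random determinant-genotype panel (by default restricted to
#' the 8 of 16 flag states that make an accession self-compatible, as any
#' real, viable accession must be) and returns the deterministic forward
#' closure of the rule engine: the full directed cross table including
#' selfs, plus the truth genotypes.
#'
#' @param n_accessions Panel size.
#' @param seed Integer seed.
#' @param self_compatible Restrict sampling to self-compatible states.
#' @return List with `genotypes` and `outcomes`.
#' @export
sim_cross_panel <- function(n_accessions = 5L, seed = 1L,
                            self_compatible = TRUE) {
  states <- expand.grid(P = c(FALSE, TRUE), S = c(FALSE, TRUE),
                        bp = c(FALSE, TRUE), bs = c(FALSE, TRUE))
  if (self_compatible) {
    ok <- vapply(seq_len(nrow(states)), function(i)
      rule_outcome(states$P[i], states$S[i], states$bp[i],
                   states$bs[i]) == "compatible", logical(1))
    states <- states[ok, , drop = FALSE]
  }
  pick <- with_seed(seed, sample(nrow(states), n_accessions,
                                 replace = TRUE))
  g <- determinant_genotype(sprintf("ACC%02d", seq_len(n_accessions)),
                            states$P[pick], states$S[pick],
                            states$bp[pick], states$bs[pick])
  list(genotypes = g, outcomes = forward_panel(g))
}
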