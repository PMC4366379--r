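#' Pea accession panel
#'
#' The five accessions of the pea cross-compatibility panel: the cultivated
#' tester line WL1238 (reference) and the wild accessions JI1794, 721
#' (compatible cytoplasms) and L100, VIR320 (cytoplasms incompatible with
#' the WL1238 nuclear background).
#'
#' @return Character vector of accession labels, reference first.
#' @export
pea_accessions <- function() c("WL1238", "JI1794", "721", "L100", "VIR320")

#' @rdname pea_accessions
#' @export
pea_phenotypes <- function() {
  c(WL1238 = "reference", JI1794 = "compatible_cytoplasm",
    `721` = "compatible_cytoplasm", L100 = "incompatible_cytoplasm",
    VIR320 = "incompatible_cytoplasm")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic filler residues: no C (reserved for the zinc finger), no E
# (reserved for poly-E runs), no M.
filler_residues <- function(n, seed) {
  pool <- c("A", "D", "F", "G", "H", "I", "K", "L", "N", "P", "Q", "R",
            "S", "T", "V", "W", "Y")
  with_seed(seed, sample(pool, n, replace = TRUE))
}

#' Reference protein profiles for the bundled variation tables
#'
#' Alignment-frame profile of the WL1238 (reference) product: a character
#' string over amino-acid letters and `-`, one character per alignment
#' column. All residues named in the bundled variation tables, the tandem
#' ISDTND hexapeptide block, the zinc-finger cysteines and the poly-E run
#' sit at their tabulated columns; remaining positions carry deterministic
#' synthetic filler (the underlying full-length sequences are not published
#' in machine-readable form). Columns occupied only by insertions relative
#' to WL1238 are `-`.
#'
#' @return Single character string (610 columns for the carboxyltransferase
#'   beta-subunit table, 290 for the biotin carboxyl carrier protein
#'   table).
#' @export
accd_reference_profile <- function() {
  prof <- filler_residues(610L, seed = 20150319L)
  set_at <- function(prof, start, what) {
    ch <- strsplit(what, "")[[1]]
    prof[start:(start + length(ch) - 1L)] <- ch
    prof
  }
  prof <- set_at(prof, 1L, "MINEDPSSLTD")
  prof <- set_at(prof, 46L, "DKI")
  prof[109L] <- "R"; prof[112L] <- "I"; prof[116L] <- "R"
  prof <- set_at(prof, 124L, "ISDTNDISDTND")
  prof <- set_at(prof, 151L, "ISDTND")
  prof <- set_at(prof, 196L, "TNIKDICE")
  prof[210L] <- "P"; prof[214L] <- "E"
  prof <- set_at(prof, 224L, "SD")
  prof[c(228L, 231L, 247L, 250L)] <- "C"
  prof[240L] <- "E"; prof[249L] <- "Q"
  prof <- set_at(prof, 340L, "EEE")
  prof[345L] <- "Q"
  prof <- set_at(prof, 375L, "HP")
  prof[379L] <- "E"; prof[383L] <- "N"; prof[384L] <- "Q"
  prof <- set_at(prof, 396L, "EEE")
  prof[407L] <- "Q"; prof[559L] <- "E"
  # columns present only as insertions in other accessions
  prof[c(141:143, 175:180, 399:401, 603:610)] <- "-"
  # keep filler free of stray C/E (pool already excludes them) and of
  # accidental cysteines next to the zinc finger; nothing more to do.
  paste(prof, collapse = "")
}

#' @rdname accd_reference_profile
#' @export
bccp3_reference_profile <- function() {
  prof <- filler_residues(290L, seed = 11410363L)
  prof[70L] <- "T"; prof[130L] <- "M"; prof[135L] <- "S"
  prof[159L] <- "M"; prof[179L] <- "A"; prof[211L] <- "M"
  prof[252L] <- "H"; prof[254L] <- "V"; prof[279L] <- "M"
  paste(prof, collapse = "")
}

load_variation_tsv <- function(file, profile, reference = "WL1238",
                               extra_attr = list()) {
  path <- system.file("extdata", file, package = "plastidcompat",
                      mustWork = TRUE)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  fixed <- c("start", "end", "kind", "ref", "alt")
  accs <- setdiff(names(d), fixed)
  prof <- strsplit(profile, "")[[1]]
  starts <- as.integer(d$start); ends <- as.integer(d$end)
  ref <- d$ref; alt <- d$alt
  for (i in seq_along(ref)) {
    span_ref <- paste(prof[starts[i]:ends[i]][prof[starts[i]:ends[i]] != "-"],
                      collapse = "")
    if (ref[i] == ".") {
      ref[i] <- span_ref
    } else if (d$kind[i] %in% c("replacement", "deletion",
                                "terminal_absence") &&
               !identical(ref[i], span_ref)) {
      stop("profile disagrees with tabulated residues at columns ",
           starts[i], "-", ends[i], " (", span_ref, " vs ", ref[i], ")")
    }
  }
  alt[alt == "."] <- ""
  ref[d$kind %in% c("insertion", "terminal_addition")] <- ""
  occ <- vapply(seq_along(starts), function(i)
    paste(sort(accs[d[i, accs] == "1"]), collapse = ","), character(1))
  out <- data.frame(start = starts, end = ends, kind = d$kind, ref = ref,
                    alt = alt, n_residues = ends - starts + 1L,
                    accessions = occ, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$kind, out$alt, out$accessions), ,
             drop = FALSE]
  rownames(out) <- NULL
  attrs <- c(list(alignment_length = nchar(profile), reference = reference,
                  acc_set = sort(accs)), extra_attr)
  for (a in names(attrs)) attr(out, a) <- attrs[[a]]
  class(out) <- c("variable_position_table", class(out))
  out
}

#' Bundled variable-position tables
#'
#' Curated tables of amino-acid differences, in alignment-column
#' coordinates, between the WL1238 reference product and the four wild-pea
#' products: one for the plastid carboxyltransferase beta subunit (accD;
#' 610-column alignment) and one for the nuclear biotin carboxyl carrier
#' protein (Bccp3; 290 columns, whose four VIR320/L100-exclusive
#' substitutions all lie in the annotated biotinyl domain, stored as the
#' `biotinyl_domain` attribute).
#'
#' @return A [variable_position_table()].
#' @export
accd_variation_table <- function() {
  load_variation_tsv("accd_variable_positions.tsv", accd_reference_profile())
}

#' @rdname accd_variation_table
#' @export
bccp3_variation_table <- function() {
  load_variation_tsv("bccp3_variable_positions.tsv",
                     bccp3_reference_profile(),
                     extra_attr = list(biotinyl_domain = c(200L, 290L)))
}

#' Reconstruct an aligned protein set from a variation table
#'
#' Applies each tabulated difference to the reference profile to rebuild
#' the full aligned sequence of every accession; the exact inverse of
#' [variable_position_table()] on these fixtures.
#'
#' @param table A [variable_position_table()].
#' @param profile Reference profile string (defaults to the matching
#'   bundled profile by alignment length).
#' @return A `protein_alignment` character matrix, reference row first.
#' @export
reconstruct_alignment <- function(table, profile = NULL) {
  stopifnot(inherits(table, "variable_position_table"))
  if (is.null(profile)) {
    profile <- switch(as.character(attr(table, "alignment_length")),
                      "610" = accd_reference_profile(),
                      "290" = bccp3_reference_profile(),
                      stop("no bundled profile for this alignment length; ",
                           "supply one"))
  }
  prof <- strsplit(profile, "")[[1]]
  L <- length(prof)
  stopifnot(L == attr(table, "alignment_length"))
  accs <- attr(table, "acc_set")
  ref_name <- attr(table, "reference")
  aln <- matrix(rep(prof, length(accs) + 1L), nrow = length(accs) + 1L,
                byrow = TRUE, dimnames = list(c(ref_name, accs), NULL))
  for (i in seq_len(nrow(table))) {
    occ <- strsplit(table$accessions[i], ",", fixed = TRUE)[[1]]
    cols <- table$start[i]:table$end[i]
    kind <- table$kind[i]
    for (a in occ) {
      if (kind %in% c("deletion", "terminal_absence")) {
        aln[a, cols] <- "-"
      } else {
        aln[a, cols] <- strsplit(table$alt[i], "")[[1]]
      }
    }
  }
  structure(aln, class = c("protein_alignment", class(aln)))
}

#' @rdname accd_variation_table
#' @export
accd_alignment <- function() reconstruct_alignment(accd_variation_table())

#' @rdname accd_variation_table
#' @export
bccp3_alignment <- function() reconstruct_alignment(bccp3_variation_table())

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Ungapped derived protein sequences from a bundled alignment
#'
#' @param aln A `protein_alignment`.
#' @return Named character vector of ungapped sequences.
#' @export
alignment_sequences <- function(aln) {
  aln <- as_alignment(aln)
  vapply(seq_len(nrow(aln)), function(i)
    degap(paste(aln[i, ], collapse = "")), character(1)) |>
    stats::setNames(rownames(aln))
}

#' The 88-line recombinant inbred mapping population
#'
#' Fixture encoding the F6 RIL population of the WL1238 x VIR320 cross
#' scored at the linkage-group III loci PhlC, Bccp3 and AJ832139 plus the
#' phenotype-assigned Scs1 genotype: 83 non-recombinant lines and five
#' crossovers between PhlC and AJ832139, three of which carry the
#' PhlC-type Bccp3 allele and two the AJ832139-type allele; Scs1
#' cosegregates with Bccp3 in all 88 lines.
#'
#' @return Character matrix (88 lines x 4 loci) over `A` (WL1238-type) /
#'   `B` (VIR320-type), class `ril_table`.
#' @export
pea_ril_table <- function() {
  patt <- c(rep("AAA", 42L), rep("BBB", 41L),
            "AAB", "AAB", "BBA",      # Bccp3 follows PhlC
            "ABB", "BAA")             # Bccp3 follows AJ832139
  g <- do.call(rbind, strsplit(patt, ""))
  g <- cbind(g, g[, 2])               # Scs1 == Bccp3
  dimnames(g) <- list(sprintf("RIL%02d", seq_len(nrow(g))),
                      c("PhlC", "Bccp3", "AJ832139", "Scs1"))
  structure(g, class = c("ril_table", class(g)))
}

#' Observed cross-compatibility outcomes among the pea accessions
#'
#' The directed crosses with unambiguous outcomes among WL1238, JI1794,
#' 721, L100 and VIR320 (cytoplasm donor written first). The 721 x VIR320
#' cross, whose published class does not disambiguate the vacant
#' secondary-binding-site qualifier, is excluded. Selfs (all compatible)
#' can be appended for inference.
#'
#' @param include_selfs Append one compatible self per accession.
#' @return `data.frame` with columns `cytoplasm_donor`, `nuclear_donor`,
#'   `outcome`.
#' @export
pea_cross_outcomes <- function(include_selfs = FALSE) {
  path <- system.file("extdata", "pea_cross_outcomes.tsv",
                      package = "plastidcompat", mustWork = TRUE)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (include_selfs) {
    d <- rbind(d, data.frame(cytoplasm_donor = pea_accessions(),
                             nuclear_donor = pea_accessions(),
                             outcome = "compatible",
                             stringsAsFactors = FALSE))
  }
  d
}
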