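#' Simulation configuration for a plastome panel
#'
#' Describes a desk-scale plastome panel: gene models for the reference,
#' the accession panel with cytoplasm phenotypes, and a list of variants
#' to plant with a per-variant presence pattern. Same seed and config give
#' byte-identical output.
#'
#' @param seed Integer seed governing all draws.
#' @param loci `data.frame` with columns `name`, `n_codons`, `strand`,
#'   `intron` (logical: split the CDS by an intron).
#' @param spacer_len Length range `c(min, max)` for intergenic spacers.
#' @param intron_len Length range for introns.
#' @param accessions Non-reference accession labels.
#' @param reference_name Reference accession label.
#' @param phenotypes Named phenotype vector over all accessions (labels
#'   `reference`, `compatible_cytoplasm`, `incompatible_cytoplasm`).
#' @param variants `data.frame` with columns `locus` (feature name),
#'   `type` (`substitution`/`insertion`/`deletion`), `effect` (target
#'   effect class), `pattern` (`"incompatible"`, `"all"`, or a
#'   comma-separated accession subset).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, loci, spacer_len = c(300L, 700L),
                       intron_len = c(150L, 300L),
                       accessions, reference_name = "REF",
                       phenotypes, variants) {
  stopifnot(all(c("name", "n_codons", "strand", "intron") %in% names(loci)),
            all(c("locus", "type", "effect", "pattern") %in%
                  names(variants)))
  structure(list(seed = as.integer(seed), loci = loci,
                 spacer_len = spacer_len, intron_len = intron_len,
                 accessions = accessions, reference_name = reference_name,
                 phenotypes = phenotypes, variants = variants),
            class = "sim_config")
}

nonstop_codons <- function() {
  gc <- plastid_code()
  names(gc)[gc != "*"]
}

random_codons <- function(n) {
  paste(sample(nonstop_codons(), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a reference plastome and an accession panel with planted
#' variants
#'
#' Builds an annotated reference (alternating intergenic spacers and
#' valid CDS gene models, some intron-split, both strands), plants each
#' configured variant at a position engineered to produce the requested
#' effect class (checked to be stable under indel left-normalisation and
#' separated from other plants), and applies the variants to each
#' accession according to its presence pattern. The truth list uses the
#' same schema as the variant-screen output.
#'
#' @param config A [sim_config()].
#' @return List with `reference` ([annotated_genome()]), `genomes` (named
#'   list of accession genomes with coordinate-shifted annotations),
#'   `truth` (a `presence_matrix` of planted variants) and `phenotypes`.
#' @export
sim_genome_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, build_genome_panel(config))
}

build_genome_panel <- function(config) {
  loci <- config$loci
  seq_parts <- character()
  features <- list()
  pos <- 0L
  add_feature <- function(locus, kind, start, end, strand,
                          phase = NA_integer_) {
    features[[length(features) + 1L]] <<- data.frame(
      locus = locus, kind = kind, start = start, end = end,
      strand = strand, phase = phase, stringsAsFactors = FALSE)
  }
  add_seq <- function(s) {
    seq_parts[[length(seq_parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  prev <- "start"
  for (i in seq_len(nrow(loci))) {
    sp_len <- sample(config$spacer_len[1]:config$spacer_len[2], 1L)
    sp_name <- paste0(prev, "-", loci$name[i])
    add_feature(sp_name, "intergenic_spacer", pos + 1L, pos + sp_len, "+")
    add_seq(random_dna(sp_len))
    cds <- paste0("ATG", random_codons(loci$n_codons[i] - 2L),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    if (loci$strand[i] == "-") cds_genomic <- revcomp(cds)
    else cds_genomic <- cds
    if (isTRUE(loci$intron[i])) {
      # split the CDS at a codon boundary around the middle
      cut <- 3L * (loci$n_codons[i] %/% 2L)
      in_len <- sample(config$intron_len[1]:config$intron_len[2], 1L)
      if (loci$strand[i] == "+") {
        add_feature(loci$name[i], "CDS", pos + 1L, pos + cut, "+", 0L)
        add_seq(substr(cds, 1L, cut))
        add_feature(paste0(loci$name[i], ".intron"), "intron",
                    pos + 1L, pos + in_len, "+")
        add_seq(random_dna(in_len))
        add_feature(loci$name[i], "CDS", pos + 1L,
                    pos + nchar(cds) - cut, "+", as.integer(cut %% 3L))
        add_seq(substr(cds, cut + 1L, nchar(cds)))
      } else {
        # genomic order: second exon (revcomp), intron, first exon
        ex2 <- substr(cds, cut + 1L, nchar(cds))
        add_feature(loci$name[i], "CDS", pos + 1L, pos + nchar(ex2), "-",
                    as.integer(cut %% 3L))
        add_seq(revcomp(ex2))
        add_feature(paste0(loci$name[i], ".intron"), "intron",
                    pos + 1L, pos + in_len, "-")
        add_seq(random_dna(in_len))
        add_feature(loci$name[i], "CDS", pos + 1L, pos + cut, "-", 0L)
        add_seq(substr(cds, 1L, cut))
      }
    } else {
      add_feature(loci$name[i], "CDS", pos + 1L, pos + nchar(cds),
                  loci$strand[i], 0L)
      add_seq(cds_genomic)
    }
    prev <- loci$name[i]
  }
  sp_len <- sample(config$spacer_len[1]:config$spacer_len[2], 1L)
  add_feature(paste0(prev, "-end"), "intergenic_spacer", pos + 1L,
              pos + sp_len, "+")
  add_seq(random_dna(sp_len))
  refseq <- paste(seq_parts, collapse = "")
  feat <- do.call(rbind, features)
  reference <- annotated_genome(config$reference_name, refseq, feat)

  plants <- plant_variants(reference, config)
  truth <- plants$variants
  # presence matrix
  accs <- config$accessions
  present <- matrix(FALSE, nrow(truth), length(accs) + 1L,
                    dimnames = list(NULL, c(config$reference_name, accs)))
  for (i in seq_len(nrow(truth))) {
    patt <- plants$pattern[i]
    inc <- names(config$phenotypes)[config$phenotypes ==
                                      "incompatible_cytoplasm"]
    in_acc <- if (patt == "incompatible") inc
              else if (patt == "all") accs
              else strsplit(patt, ",", fixed = TRUE)[[1]]
    present[i, in_acc] <- TRUE
  }
  genomes <- lapply(accs, function(a) {
    apply_variants(reference, truth[present[, a], , drop = FALSE], a)
  })
  names(genomes) <- accs
  tm <- structure(list(variants = truth, present = present,
                       phenotypes = config$phenotypes[
                         c(config$reference_name, accs)]),
                  class = "presence_matrix")
  list(reference = reference, genomes = genomes, truth = tm,
       phenotypes = config$phenotypes)
}

plant_variants <- function(reference, config, min_gap = 60L,
                           max_tries = 500L) {
  used <- matrix(numeric(0), ncol = 2)   # occupied spans (with padding)
  free_at <- function(s, e) {
    !nrow(used) || all(used[, 2] < s - min_gap | used[, 1] > e + min_gap)
  }
  reserve <- function(s, e) used <<- rbind(used, c(s, e))
  feat <- reference$features
  refseq <- reference$seq
  base_at <- function(p) substr(refseq, p, p)
  rows <- list()
  vs <- config$variants
  for (i in seq_len(nrow(vs))) {
    f <- feat[feat$locus == vs$locus[i], , drop = FALSE]
    if (!nrow(f)) stop("variant locus '", vs$locus[i],
                       "' not in reference annotation")
    rec <- NULL
    for (try in seq_len(max_tries)) {
      rec <- try_plant(reference, f, vs$type[i], vs$effect[i])
      if (!is.null(rec) && free_at(rec$ref_start, max(rec$ref_end,
                                                      rec$ref_start)))
        break
      rec <- NULL
    }
    if (is.null(rec))
      stop("could not place variant ", i, " (", vs$type[i], "/",
           vs$effect[i], ") in locus '", vs$locus[i], "'")
    reserve(rec$ref_start, max(rec$ref_end, rec$ref_start))
    rec$locus <- vs$locus[i]
    rec$region <- f$kind[1]
    rec$effect <- vs$effect[i]
    rows[[length(rows) + 1L]] <- rec
  }
  variants <- do.call(rbind, c(list(empty_variants()), rows))
  ord <- order(variants$ref_start, variants$ref_end)
  list(variants = variants[ord, , drop = FALSE],
       pattern = vs$pattern[ord])
}

# Attempt to construct one variant of the requested type/effect inside
# feature f (possibly multi-segment CDS). Returns a one-row variant df or
# NULL.
try_plant <- function(reference, f, type, effect) {
  refseq <- reference$seq
  locus <- f$locus[1]
  kind <- f$kind[1]
  if (effect == "noncoding") {
    s <- f$start[1]; e <- f$end[1]
    if (e - s < 40L) return(NULL)
    p <- sample((s + 15L):(e - 15L), 1L)
    if (type == "substitution") {
      ref <- substr(refseq, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      return(variant_record(p, p, "substitution", ref, alt))
    } else if (type == "deletion") {
      len <- sample(1:4, 1L)
      rec <- variant_record(p, p + len - 1L, "deletion",
                            substr(refseq, p, p + len - 1L), "")
      return(stable_indel(rec, refseq))
    } else {
      alt <- random_dna(sample(1:4, 1L))
      rec <- variant_record(p, p - 1L, "insertion", "", alt)
      return(stable_indel(rec, refseq))
    }
  }
  # coding effects: work in CDS-local codon space
  cds <- cds_sequence(reference, locus)
  n_codon <- nchar(cds) %/% 3L
  strand <- f$strand[1]
  codon_at <- function(ci) substr(cds, 3L * ci - 2L, 3L * ci)
  # genome position of CDS-local position lp
  genome_pos <- function(lp) {
    cs <- cds_segments(reference, locus)
    off <- 0L
    for (j in seq_len(nrow(cs$segments))) {
      w <- cs$segments$end[j] - cs$segments$start[j] + 1L
      if (lp <= off + w) {
        return(if (cs$strand == "+") cs$segments$start[j] + (lp - off) - 1L
               else cs$segments$end[j] - (lp - off) + 1L)
      }
      off <- off + w
    }
    stop("CDS-local position out of range")
  }
  gc <- plastid_code()
  sub_at <- function(lp, alt_coding) {
    # alt_coding: replacement base on the coding strand at local pos lp
    gp <- genome_pos(lp)
    ref <- substr(refseq, gp, gp)
    alt <- if (strand == "+") alt_coding else revcomp(alt_coding)
    if (identical(ref, alt)) return(NULL)
    variant_record(gp, gp, "substitution", ref, alt)
  }
  if (effect == "synonymous" || effect == "nonsynonymous") {
    ci <- sample(3:(n_codon - 2L), 1L)
    cod <- codon_at(ci)
    aa <- unname(gc[cod])
    pos_in <- if (effect == "synonymous") 3L else sample(1:3, 1L)
    for (b in sample(setdiff(c("A", "C", "G", "T"),
                             substr(cod, pos_in, pos_in)))) {
      alt_cod <- cod
      substr(alt_cod, pos_in, pos_in) <- b
      alt_aa <- unname(gc[alt_cod])
      ok <- if (effect == "synonymous") identical(alt_aa, aa)
            else !identical(alt_aa, aa) && alt_aa != "*"
      if (ok) return(sub_at(3L * (ci - 1L) + pos_in, b))
    }
    return(NULL)
  }
  if (effect == "inframe_indel") {
    ci <- sample(3:(n_codon - 3L), 1L)
    if (type == "deletion") {
      lp0 <- 3L * ci - 2L
      gp <- sort(c(genome_pos(lp0), genome_pos(lp0 + 2L)))
      # stay within one CDS segment
      if (gp[2] - gp[1] != 2L) return(NULL)
      rec <- variant_record(gp[1], gp[2], "deletion",
                            substr(refseq, gp[1], gp[2]), "")
    } else {
      lp0 <- 3L * ci
      gp <- genome_pos(lp0)
      ins <- random_codons(1L)
      if (strand == "-") { ins <- revcomp(ins); gp <- gp - 1L }
      rec <- variant_record(gp + 1L, gp, "insertion", "", ins)
    }
    return(stable_indel(rec, refseq))
  }
  if (effect == "frameshift") {
    ci <- sample(3:(n_codon - 3L), 1L)
    gp <- genome_pos(3L * ci - 1L)
    rec <- variant_record(gp, gp, "deletion", substr(refseq, gp, gp), "")
    return(stable_indel(rec, refseq))
  }
  if (effect == "start_loss") {
    gp <- genome_pos(1L)   # the A of ATG on the coding strand
    return(sub_at(1L, "C"))
  }
  if (effect == "stop_loss_extension") {
    # mutate the middle base of the stop codon to give a sense codon
    lp <- 3L * n_codon - 1L
    cod <- codon_at(n_codon)
    for (b in sample(setdiff(c("A", "C", "G", "T"), substr(cod, 2, 2)))) {
      alt_cod <- cod
      substr(alt_cod, 2, 2) <- b
      if (unname(gc[alt_cod]) != "*") return(sub_at(lp, b))
    }
    return(NULL)
  }
  stop("unsupported planted effect '", effect, "'")
}

# A planted indel must already be in left-normal form, so that calls and
# truth coincide exactly.
stable_indel <- function(rec, refseq) {
  norm <- left_normalize(rec, refseq)
  if (norm$ref_start == rec$ref_start &&
      identical(norm$alt_allele, rec$alt_allele)) rec else NULL
}

# Apply a variant set to the reference, shifting the annotation.
apply_variants <- function(reference, variants, id) {
  seq <- reference$seq
  v <- variants[order(-variants$ref_start), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    if (v$type[i] == "substitution") {
      substr(seq, v$ref_start[i], v$ref_end[i]) <- v$alt_allele[i]
    } else if (v$type[i] == "deletion") {
      seq <- paste0(substr(seq, 1L, v$ref_start[i] - 1L),
                    substr(seq, v$ref_end[i] + 1L, nchar(seq)))
    } else if (v$type[i] == "insertion") {
      p <- v$ref_start[i] - 1L
      seq <- paste0(substr(seq, 1L, p), v$alt_allele[i],
                    substr(seq, p + 1L, nchar(seq)))
    }
  }
  # shift feature coordinates by the cumulative indel deltas
  deltas <- variants[variants$type != "substitution", , drop = FALSE]
  shift <- function(x) {
    if (!nrow(deltas)) return(x)
    d <- 0L
    for (i in seq_len(nrow(deltas))) {
      len <- nchar(deltas$alt_allele[i]) - nchar(deltas$ref_allele[i])
      anchor <- if (deltas$type[i] == "deletion") deltas$ref_end[i]
                else deltas$ref_start[i] - 1L
      if (anchor < x) d <- d + len
    }
    x + d
  }
  feat <- reference$features
  feat$start <- vapply(feat$start, shift, numeric(1))
  feat$end <- vapply(feat$end, shift, numeric(1))
  annotated_genome(id, seq, feat)
}

#' Study-like screening configuration
#'
#' A [sim_config()] reproducing the screening conditions of the pea
#' panel: four wild accessions against a cultivated reference, with 37
#' variants planted in the incompatible-cytoplasm pattern - 14
#' non-synonymous substitutions and 3 indels in the four candidate loci
#' (8+3 in accD, 1 in rpoB, 3 in ycf1, 2 in ycf2), 5 synonymous
#' substitutions in three further coding loci, and 15 noncoding variants
#' across 14 noncoding regions - plus 9 decoy variants in other presence
#' patterns.
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
pea_screen_config <- function(seed = 1L) {
  loci <- data.frame(
    name = c("psbA", "matK", "atpA", "atpF", "rpoB", "accD", "psaA",
             "ycf1", "ycf2", "rbcL", "rpl2", "petB"),
    n_codons = c(160L, 170L, 180L, 150L, 250L, 590L, 200L, 300L, 300L,
                 160L, 150L, 150L),
    strand = c("+", "+", "+", "+", "-", "+", "+", "+", "+", "+", "+",
               "-"),
    intron = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
               FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  inc <- "incompatible"
  v <- rbind(
    # accD: 8 non-synonymous substitutions + 3 indels
    data.frame(locus = "accD", type = "substitution",
               effect = "nonsynonymous", pattern = inc)[rep(1, 8), ],
    data.frame(locus = "accD", type = c("deletion", "insertion",
                                        "deletion"),
               effect = c("inframe_indel", "inframe_indel", "frameshift"),
               pattern = inc),
    data.frame(locus = "rpoB", type = "substitution",
               effect = "nonsynonymous", pattern = inc),
    data.frame(locus = "ycf1", type = "substitution",
               effect = "nonsynonymous", pattern = inc)[rep(1, 3), ],
    data.frame(locus = "ycf2", type = "substitution",
               effect = "nonsynonymous", pattern = inc)[rep(1, 2), ],
    # 5 synonymous in three further loci
    data.frame(locus = c("psbA", "psbA", "rbcL", "rbcL", "matK"),
               type = "substitution", effect = "synonymous",
               pattern = inc),
    # 15 noncoding variants in 14 noncoding regions
    data.frame(locus = c("start-psbA", "start-psbA", "psbA-matK",
                         "matK-atpA", "atpA-atpF", "atpF-rpoB",
                         "rpoB-accD", "accD-psaA", "psaA-ycf1",
                         "ycf1-ycf2", "ycf2-rbcL", "rbcL-rpl2",
                         "rpl2-petB", "atpF.intron", "rpl2.intron"),
               type = c("substitution", "deletion", "substitution",
                        "substitution", "insertion", "substitution",
                        "substitution", "substitution", "deletion",
                        "substitution", "substitution", "insertion",
                        "substitution", "substitution", "substitution"),
               effect = "noncoding", pattern = inc),
    # decoys in other presence patterns
    data.frame(locus = "psaA", type = "substitution",
               effect = "nonsynonymous", pattern = "all"),
    data.frame(locus = c("petB-end", "start-psbA"),
               type = "substitution", effect = "noncoding",
               pattern = "all"),
    data.frame(locus = c("petB", "matK-atpA"),
               type = "substitution",
               effect = c("nonsynonymous", "noncoding"),
               pattern = "JI1794"),
    data.frame(locus = c("atpA", "ycf2-rbcL"),
               type = "substitution",
               effect = c("synonymous", "noncoding"),
               pattern = "721"),
    data.frame(locus = "accD-psaA", type = "substitution",
               effect = "noncoding", pattern = "VIR320"),
    data.frame(locus = "rpoB-accD", type = "substitution",
               effect = "noncoding", pattern = "721,L100"))
  sim_config(seed = seed, loci = loci,
             accessions = c("JI1794", "721", "L100", "VIR320"),
             reference_name = "WL1238",
             phenotypes = pea_phenotypes(),
             variants = v)
}

#' Gap-length accounting fixture
#'
#' Builds a reference genome and a re-sequenced genome whose assembly
#' contains `N`-gaps: each gap replaces a reference region of the given
#' length by a placeholder run of `N`s, so that [effective_length()]
#' recovers `resolved_len + sum(region_lens)`.
#'
#' @param seed Integer seed.
#' @param resolved_len Total resolved (non-gap) sequence length of the
#'   re-sequenced genome.
#' @param region_lens Reference-region length of each gap.
#' @param gap_lens Placeholder `N`-run length of each gap.
#' @return List with `reference`, `genome` (both [annotated_genome()]).
#' @export
sim_gap_fixture <- function(seed = 1L, resolved_len = 121529L,
                            region_lens = c(258L, 37L),
                            gap_lens = c(100L, 20L)) {
  k <- length(region_lens)
  stopifnot(length(gap_lens) == k)
  with_seed(seed, {
    # split the resolved sequence into k+1 blocks
    cut <- sort(sample(seq(2000L, resolved_len - 2000L, by = 100L), k))
    bounds <- c(0L, cut, resolved_len)
    blocks <- vapply(seq_len(k + 1L), function(i)
      random_dna(bounds[i + 1L] - bounds[i]), character(1))
    regions <- vapply(region_lens, random_dna, character(1))
    ref_parts <- character(2L * k + 1L)
    gen_parts <- character(2L * k + 1L)
    gaps <- empty_gaps()
    pos <- 0L
    for (i in seq_len(k + 1L)) {
      ref_parts[2L * i - 1L] <- blocks[i]
      gen_parts[2L * i - 1L] <- blocks[i]
      pos <- pos + nchar(blocks[i])
      if (i <= k) {
        ref_parts[2L * i] <- regions[i]
        gen_parts[2L * i] <- strrep("N", gap_lens[i])
        gaps <- rbind(gaps, data.frame(start = pos + 1L,
                                       end = pos + gap_lens[i]))
        pos <- pos + gap_lens[i]
      }
    }
    list(reference = annotated_genome("REF",
                                      paste(ref_parts, collapse = "")),
         genome = annotated_genome("RESEQ",
                                   paste(gen_parts, collapse = ""),
                                   gaps = gaps))
  })
}
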