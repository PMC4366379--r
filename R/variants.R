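#' @name variant_table
#' @title Variant table schema
#' @description
#' Variants are plain `data.frame`s with columns `ref_start`, `ref_end`
#' (1-based inclusive on the reference; an insertion between reference
#' positions p and p+1 has `ref_start = p + 1`, `ref_end = p`), `type`
#' (`substitution`, `insertion`, `deletion`, `inversion`), `ref_allele`,
#' `alt_allele`, `locus`, `region` (`CDS`, `intron`, `intergenic_spacer`)
#' and `effect` (`synonymous`, `nonsynonymous`, `inframe_indel`,
#' `frameshift`, `start_loss`, `stop_loss_extension`, `noncoding`).
NULL

variant_effects <- c("synonymous", "nonsynonymous", "inframe_indel",
                     "frameshift", "start_loss", "stop_loss_extension",
                     "noncoding")

empty_variants <- function() {
  data.frame(ref_start = integer(), ref_end = integer(), type = character(),
             ref_allele = character(), alt_allele = character(),
             locus = character(), region = character(), effect = character(),
             stringsAsFactors = FALSE)
}

plastid_code <- function() Biostrings::getGeneticCode("11")

translate_cds <- function(dna, to_stop = TRUE) {
  gc <- plastid_code()
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  if (to_stop) {
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  }
  paste(aa, collapse = "")
}

is_stop_codon <- function(codon) {
  !is.na(codon) && nchar(codon) == 3L &&
    identical(unname(plastid_code()[codon]), "*")
}

revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## ---------------------------------------------------------------------------
## Pairwise plastome comparison

#' Call variants between two colinear genomes
#'
#' Anchor-based global comparison: exact-match k-mers unique in both
#' genomes are chained colinearly; the short unanchored segments in
#' between are aligned with Needleman-Wunsch
#' ([Biostrings::pairwiseAlignment()]) and differences are emitted as
#' left-normalised variant records, annotated with locus, region and
#' coding effect against the reference annotation. Adjacent substituted
#' bases within one codon of a CDS are merged into a single
#' multi-nucleotide record; an inverted segment is reported as a flagged
#' `inversion` record with breakpoint spans and no effect classification.
#'
#' @param reference,query [annotated_genome()] objects; the reference
#'   carries the feature annotation used for effect classification.
#' @param k Anchor k-mer length.
#' @param min_anchor_frac Minimum fraction of the shorter genome that must
#'   be covered by the colinear anchor chain; below this the genomes are
#'   declared "not colinear".
#' @return A variant `data.frame` (see [variant_table]) sorted by
#'   `ref_start`.
#' @export
align_and_call <- function(reference, query, k = 21L,
                           min_anchor_frac = 0.5) {
  stopifnot(inherits(reference, "annotated_genome"),
            inherits(query, "annotated_genome"))
  rs <- reference$seq; qs <- query$seq
  if (identical(rs, qs)) return(empty_variants())

  ch <- anchor_chain(rs, qs, k)
  cov <- sum(ch$chain$rend - ch$chain$rstart + 1L)
  if (cov < min_anchor_frac * min(nchar(rs), nchar(qs)))
    stop("genomes '", reference$id, "' and '", query$id,
         "' are not colinear (anchor coverage ",
         round(cov / min(nchar(rs), nchar(qs)), 2), ")")

  out <- list()
  blocks <- ch$chain
  nb <- nrow(blocks)
  seg <- function(rlo, rhi, qlo, qhi) {
    rseg <- if (rlo <= rhi) substr(rs, rlo, rhi) else ""
    qseg <- if (qlo <= qhi) substr(qs, qlo, qhi) else ""
    call_segment(rseg, qseg, rlo, reference, query)
  }
  # head
  if (blocks$rstart[1] > 1L || blocks$qstart[1] > 1L)
    out[[length(out) + 1L]] <- seg(1L, blocks$rstart[1] - 1L,
                                   1L, blocks$qstart[1] - 1L)
  for (i in seq_len(nb - 1L)) {
    out[[length(out) + 1L]] <- seg(blocks$rend[i] + 1L,
                                   blocks$rstart[i + 1L] - 1L,
                                   blocks$qend[i] + 1L,
                                   blocks$qstart[i + 1L] - 1L)
  }
  # tail
  if (blocks$rend[nb] < nchar(rs) || blocks$qend[nb] < nchar(qs))
    out[[length(out) + 1L]] <- seg(blocks$rend[nb] + 1L, nchar(rs),
                                   blocks$qend[nb] + 1L, nchar(qs))
  v <- do.call(rbind, c(list(empty_variants()), out))
  v <- v[order(v$ref_start, v$ref_end), , drop = FALSE]
  rownames(v) <- NULL
  v
}

# Unique-kmer colinear chain between two sequences.
anchor_chain <- function(rs, qs, k) {
  rk <- substring(rs, seq_len(nchar(rs) - k + 1L),
                  seq_len(nchar(rs) - k + 1L) + k - 1L)
  qk <- substring(qs, seq_len(nchar(qs) - k + 1L),
                  seq_len(nchar(qs) - k + 1L) + k - 1L)
  rt <- table(rk); qt <- table(qk)
  shared <- intersect(names(rt)[rt == 1L], names(qt)[qt == 1L])
  rpos <- match(shared, rk); qpos <- match(shared, qk)
  o <- order(rpos)
  rpos <- rpos[o]; qpos <- qpos[o]
  if (!length(rpos)) stop("no unique anchors shared between genomes")
  keep <- lis_indices(qpos)
  rpos <- rpos[keep]; qpos <- qpos[keep]
  # merge anchors into maximal blocks of constant offset and contiguity
  d <- qpos - rpos
  newblock <- c(TRUE, d[-1] != d[-length(d)] |
                  rpos[-1] > rpos[-length(rpos)] + k)
  grp <- cumsum(newblock)
  chain <- data.frame(
    rstart = tapply(rpos, grp, min),
    rend = tapply(rpos, grp, max) + k - 1L,
    qstart = tapply(qpos, grp, min),
    qend = tapply(qpos, grp, max) + k - 1L)
  rownames(chain) <- NULL
  # adjacent blocks may overlap by a few bases when an indel's flank
  # repeats; trim the later block (still an exact match) so segments
  # between blocks carry the whole event
  i <- 1L
  while (i < nrow(chain)) {
    ov <- max(chain$rend[i] - chain$rstart[i + 1L] + 1L,
              chain$qend[i] - chain$qstart[i + 1L] + 1L, 0L)
    if (ov > 0L) {
      chain$rstart[i + 1L] <- chain$rstart[i + 1L] + ov
      chain$qstart[i + 1L] <- chain$qstart[i + 1L] + ov
      if (chain$rstart[i + 1L] > chain$rend[i + 1L] ||
          chain$qstart[i + 1L] > chain$qend[i + 1L]) {
        chain <- chain[-(i + 1L), , drop = FALSE]
        next
      }
    }
    i <- i + 1L
  }
  rownames(chain) <- NULL
  list(chain = chain)
}

# Longest increasing subsequence (strict), O(n log n); returns indices.
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer())
  tails <- integer(0)      # indices into x of tail elements
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  res <- integer(0)
  i <- tails[length(tails)]
  while (i > 0L) { res <- c(i, res); i <- prev[i] }
  res
}

# Variant-call one unanchored segment pair. ref_offset = reference
# coordinate of the first base of rseg.
call_segment <- function(rseg, qseg, ref_offset, reference, query,
                         max_segment = 20000L) {
  if (identical(rseg, qseg)) return(empty_variants())
  if (nchar(rseg) > 200L && nchar(qseg) > 200L) {
    inv <- detect_inversion(rseg, qseg, ref_offset, reference)
    if (!is.null(inv)) return(inv)
  }
  if (nchar(rseg) > max_segment || nchar(qseg) > max_segment)
    stop("unanchored segment too large (", nchar(rseg), " vs ",
         nchar(qseg), " bp): genomes not colinear at reference position ",
         ref_offset)
  if (!nzchar(rseg)) {
    v <- variant_record(ref_offset, ref_offset - 1L, "insertion", "", qseg)
  } else if (!nzchar(qseg)) {
    v <- variant_record(ref_offset, ref_offset + nchar(rseg) - 1L,
                        "deletion", rseg, "")
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                    mismatch = -3)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(rseg), Biostrings::DNAString(qseg),
      type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    gr <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    gq <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    v <- walk_alignment(gr, gq, ref_offset)
  }
  if (nrow(v)) {
    v <- left_normalize(v, reference$seq)
    v <- merge_codon_mnvs(v, reference)
    v <- annotate_variants(v, reference)
  }
  v
}

variant_record <- function(s, e, type, ref, alt) {
  data.frame(ref_start = as.integer(s), ref_end = as.integer(e),
             type = type, ref_allele = ref, alt_allele = alt,
             locus = NA_character_, region = NA_character_,
             effect = NA_character_, stringsAsFactors = FALSE)
}

# Turn one gapped alignment (char vectors) into raw variant records.
walk_alignment <- function(gr, gq, ref_offset) {
  state <- ifelse(gr == "-", "ins", ifelse(gq == "-", "del",
                  ifelse(gr == gq, "m", "sub")))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  refpos <- cumsum(gr != "-") + ref_offset - 1L  # ref coord at column
  out <- list()
  for (i in seq_along(r$values)) {
    st <- r$values[i]
    if (st == "m") next
    a <- starts[i]; b <- ends[i]
    rseq <- paste(gr[a:b][gr[a:b] != "-"], collapse = "")
    qseq <- paste(gq[a:b][gq[a:b] != "-"], collapse = "")
    if (st == "sub") {
      out[[length(out) + 1L]] <-
        variant_record(refpos[a], refpos[b], "substitution", rseq, qseq)
    } else if (st == "del") {
      out[[length(out) + 1L]] <-
        variant_record(refpos[a], refpos[b], "deletion", rseq, "")
    } else { # ins: after ref position refpos[a] (coord of last ref base seen)
      p <- if (a == 1L) ref_offset - 1L else refpos[a]
      out[[length(out) + 1L]] <-
        variant_record(p + 1L, p, "insertion", "", qseq)
    }
  }
  do.call(rbind, c(list(empty_variants()), out))
}

# Shift indels to their leftmost equivalent placement on the reference.
left_normalize <- function(v, refseq) {
  for (i in seq_len(nrow(v))) {
    if (v$type[i] == "deletion") {
      s <- v$ref_start[i]; e <- v$ref_end[i]
      while (s > 1L && substr(refseq, s - 1L, s - 1L) ==
               substr(refseq, e, e)) {
        s <- s - 1L; e <- e - 1L
      }
      v$ref_start[i] <- s; v$ref_end[i] <- e
      v$ref_allele[i] <- substr(refseq, s, e)
    } else if (v$type[i] == "insertion") {
      p <- v$ref_start[i] - 1L  # base before insertion
      a <- v$alt_allele[i]
      while (p >= 1L && substr(refseq, p, p) ==
               substr(a, nchar(a), nchar(a))) {
        a <- paste0(substr(a, nchar(a), nchar(a)),
                    substr(a, 1L, nchar(a) - 1L))
        p <- p - 1L
      }
      v$ref_start[i] <- p + 1L; v$ref_end[i] <- p
      v$alt_allele[i] <- a
    }
  }
  v
}

# Merge adjacent single-base substitutions lying within one codon of the
# same CDS into one multi-nucleotide record.
merge_codon_mnvs <- function(v, reference) {
  if (nrow(v) < 2L) return(v)
  subs <- which(v$type == "substitution")
  if (length(subs) < 2L) return(v)
  cds <- reference$features[reference$features$kind == "CDS", , drop = FALSE]
  drop <- logical(nrow(v))
  for (j in seq_along(subs)[-1]) {
    i0 <- subs[j - 1L]; i1 <- subs[j]
    if (drop[i0]) next
    if (v$ref_start[i1] != v$ref_end[i0] + 1L) next
    loc <- cds_locus_at(cds, v$ref_start[i0])
    if (is.na(loc) || !identical(loc, cds_locus_at(cds, v$ref_end[i1]))) next
    ci <- codon_index(reference, loc, v$ref_start[i0])
    if (!identical(ci, codon_index(reference, loc, v$ref_end[i1]))) next
    v$ref_end[i0] <- v$ref_end[i1]
    v$ref_allele[i0] <- paste0(v$ref_allele[i0], v$ref_allele[i1])
    v$alt_allele[i0] <- paste0(v$alt_allele[i0], v$alt_allele[i1])
    drop[i1] <- TRUE
    subs[j] <- i0   # allow chains
  }
  v[!drop, , drop = FALSE]
}

cds_locus_at <- function(cds, pos) {
  hit <- cds$start <= pos & cds$end >= pos
  if (!any(hit)) NA_character_ else cds$locus[which(hit)[1]]
}

# Inversion: the query segment matches the reverse complement of the
# reference segment.
detect_inversion <- function(rseg, qseg, ref_offset, reference) {
  rc <- revcomp(qseg)
  k <- 21L
  if (nchar(rseg) < 2L * k || nchar(rc) < 2L * k) return(NULL)
  ch <- tryCatch(anchor_chain(rseg, rc, k), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  cov <- sum(ch$chain$rend - ch$chain$rstart + 1L)
  if (cov < 0.8 * min(nchar(rseg), nchar(rc))) return(NULL)
  v <- variant_record(ref_offset, ref_offset + nchar(rseg) - 1L,
                      "inversion", "", "")
  annotate_variants(v, reference)
}

## ---------------------------------------------------------------------------
## Effect classification

#' Classify the coding effect of a variant
#'
#' Variants outside CDS features are `noncoding`. Within a CDS (translation
#' table 11, the bacterial/plastid code): substitutions whose affected
#' codons translate identically are `synonymous`, otherwise
#' `nonsynonymous`; a substitution or indel disrupting the annotated start
#' codon is `start_loss`; a substitution turning the annotated stop codon
#' into a sense codon is `stop_loss_extension`; indels are `inframe_indel`
#' when the length change is a multiple of 3 and `frameshift` otherwise.
#' Inversions are flagged records and keep effect `NA`.
#'
#' @param variant One-row variant `data.frame` (see [variant_table]).
#' @param genome Reference [annotated_genome()] carrying the annotation.
#' @return The variant row with `locus`, `region` and `effect` filled in.
#' @export
classify_effect <- function(variant, genome) {
  annotate_variants(variant, genome)
}

annotate_variants <- function(v, genome) {
  for (i in seq_len(nrow(v))) {
    ann <- annotate_one(v[i, ], genome)
    v$locus[i] <- ann$locus
    v$region[i] <- ann$region
    v$effect[i] <- ann$effect
  }
  v
}

# Span used for feature overlap; insertions are located by their left
# flanking base.
variant_span <- function(v1) {
  if (v1$type == "insertion") c(max(v1$ref_start - 1L, 1L),
                                max(v1$ref_start - 1L, 1L))
  else c(v1$ref_start, v1$ref_end)
}

annotate_one <- function(v1, genome) {
  f <- genome$features
  sp <- variant_span(v1)
  ov <- f$start <= sp[2] & f$end >= sp[1]
  hit <- f[ov, , drop = FALSE]
  pick <- function(kind) hit[hit$kind == kind, , drop = FALSE]
  cds <- pick("CDS")
  if (nrow(cds)) {
    return(list(locus = cds$locus[1], region = "CDS",
                effect = if (v1$type == "inversion") NA_character_
                         else cds_effect(v1, genome, cds$locus[1])))
  }
  intr <- pick("intron")
  if (nrow(intr))
    return(list(locus = intr$locus[1], region = "intron",
                effect = if (v1$type == "inversion") NA_character_
                         else "noncoding"))
  igs <- pick("intergenic_spacer")
  if (nrow(igs))
    return(list(locus = igs$locus[1], region = "intergenic_spacer",
                effect = if (v1$type == "inversion") NA_character_
                         else "noncoding"))
  list(locus = NA_character_, region = "intergenic_spacer",
       effect = if (v1$type == "inversion") NA_character_ else "noncoding")
}

# CDS segments of a locus in translation order.
cds_segments <- function(genome, locus) {
  seg <- genome$features[genome$features$kind == "CDS" &
                           genome$features$locus == locus, , drop = FALSE]
  if (!nrow(seg)) stop("no CDS annotated for locus '", locus, "'")
  strand <- unique(seg$strand)
  if (length(strand) != 1L || !strand %in% c("+", "-"))
    stop("CDS '", locus, "' without consistent annotated strand")
  seg <- seg[order(seg$start), , drop = FALSE]
  if (strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  list(segments = seg, strand = strand)
}

# Spliced CDS sequence (coding strand).
cds_sequence <- function(genome, locus) {
  cs <- cds_segments(genome, locus)
  parts <- vapply(seq_len(nrow(cs$segments)), function(i) {
    s <- substr(genome$seq, cs$segments$start[i], cs$segments$end[i])
    if (cs$strand == "-") revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

# Map a genome position to a 1-based coding-strand CDS position (NA if
# outside the CDS).
cds_local_pos <- function(genome, locus, pos) {
  cs <- cds_segments(genome, locus)
  off <- 0L
  for (i in seq_len(nrow(cs$segments))) {
    s <- cs$segments$start[i]; e <- cs$segments$end[i]
    if (pos >= s && pos <= e) {
      return(off + if (cs$strand == "+") pos - s + 1L else e - pos + 1L)
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

codon_index <- function(genome, locus, pos) {
  lp <- cds_local_pos(genome, locus, pos)
  if (is.na(lp)) NA_integer_ else (lp - 1L) %/% 3L + 1L
}

cds_effect <- function(v1, genome, locus) {
  cds <- cds_sequence(genome, locus)
  n <- nchar(cds)
  cs <- cds_segments(genome, locus)
  # CDS-local span touched by the variant (clipped to the CDS)
  span <- variant_span(v1)
  touched <- span[1]:span[2]
  lp <- vapply(touched, function(p) cds_local_pos(genome, locus, p),
               integer(1))
  lp <- lp[!is.na(lp)]
  if (!length(lp)) return("noncoding")
  lo <- min(lp); hi <- max(lp)

  indel_delta <- nchar(v1$alt_allele) - nchar(v1$ref_allele)
  if (v1$type %in% c("insertion", "deletion")) {
    if (lo <= 3L && v1$type == "deletion") return("start_loss")
    if (indel_delta %% 3L != 0L) return("frameshift")
    return("inframe_indel")
  }

  # substitution: rebuild the affected part of the CDS on the coding strand
  alt_allele <- v1$alt_allele
  ref_allele <- v1$ref_allele
  if (cs$strand == "-") {
    alt_allele <- revcomp(alt_allele)
    ref_allele <- revcomp(ref_allele)
  }
  # clip allele to CDS-contained part
  inside <- !is.na(vapply(touched, function(p)
    cds_local_pos(genome, locus, p), integer(1)))
  if (cs$strand == "-") inside <- rev(inside)
  alt_in <- paste(strsplit(alt_allele, "")[[1]][inside], collapse = "")
  alt_cds <- paste0(substr(cds, 1L, lo - 1L), alt_in,
                    substr(cds, hi + 1L, n))

  if (lo <= 3L) {
    if (substr(alt_cds, 1L, 3L) != "ATG") return("start_loss")
  }
  if (hi >= n - 2L) {
    last_ref <- substr(cds, n - 2L, n)
    last_alt <- substr(alt_cds, n - 2L, n)
    if (is_stop_codon(last_ref) && !is_stop_codon(last_alt))
      return("stop_loss_extension")
  }
  c0 <- (lo - 1L) %/% 3L + 1L
  c1 <- (hi - 1L) %/% 3L + 1L
  ref_aa <- translate_cds(substr(cds, 3L * c0 - 2L, 3L * c1), to_stop = FALSE)
  alt_aa <- translate_cds(substr(alt_cds, 3L * c0 - 2L, 3L * c1),
                          to_stop = FALSE)
  if (identical(ref_aa, alt_aa)) "synonymous" else "nonsynonymous"
}

## ---------------------------------------------------------------------------
## Presence matrix and the candidate funnel

#' Build a presence/absence matrix from per-accession variant calls
#'
#' Variants are matched across accessions by position, type and alleles.
#' The reference accession is included as an all-absent column (all calls
#' are differences against it).
#'
#' @param calls Named list of variant `data.frame`s, one per accession.
#' @param reference_name Label of the reference accession.
#' @param phenotypes Named character vector mapping every accession
#'   (including the reference) to one of `incompatible_cytoplasm`,
#'   `compatible_cytoplasm`, `reference`.
#' @return A `presence_matrix`: list with `variants` (unique variant rows),
#'   `present` (logical matrix, variants x accessions) and `phenotypes`.
#' @export
build_presence_matrix <- function(calls, reference_name, phenotypes) {
  stopifnot(is.list(calls), !is.null(names(calls)))
  key <- function(v) paste(v$ref_start, v$ref_end, v$type, v$ref_allele,
                           v$alt_allele, sep = "|")
  all_v <- do.call(rbind, c(list(empty_variants()), unname(calls)))
  uniq <- all_v[!duplicated(key(all_v)), , drop = FALSE]
  uniq <- uniq[order(uniq$ref_start, uniq$ref_end), , drop = FALSE]
  rownames(uniq) <- NULL
  accs <- c(reference_name, names(calls))
  present <- matrix(FALSE, nrow(uniq), length(accs),
                    dimnames = list(NULL, accs))
  uk <- key(uniq)
  for (a in names(calls)) present[, a] <- uk %in% key(calls[[a]])
  if (!all(accs %in% names(phenotypes)))
    stop("phenotype labels missing for: ",
         paste(setdiff(accs, names(phenotypes)), collapse = ", "))
  structure(list(variants = uniq, present = present,
                 phenotypes = phenotypes[accs]),
            class = "presence_matrix")
}

#' Phenotype-pattern variant filter
#'
#' Returns the variants present in every accession labelled
#' `incompatible_cytoplasm` and absent from every accession labelled
#' `compatible_cytoplasm`, in input order.
#'
#' @param matrix_ A `presence_matrix` from [build_presence_matrix()].
#' @return The matching subset of `matrix_$variants`.
#' @export
pattern_filter <- function(matrix_) {
  stopifnot(inherits(matrix_, "presence_matrix"))
  ph <- matrix_$phenotypes
  inc <- names(ph)[ph == "incompatible_cytoplasm"]
  comp <- names(ph)[ph == "compatible_cytoplasm"]
  if (!length(inc) || !length(comp))
    stop("need at least one incompatible_cytoplasm and one ",
         "compatible_cytoplasm accession label")
  p <- matrix_$present
  keep <- rowSums(p[, inc, drop = FALSE]) == length(inc) &
    rowSums(p[, comp, drop = FALSE]) == 0L
  out <- matrix_$variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate loci from pattern-filtered variants
#'
#' Drops noncoding and synonymous variants, groups the remainder by locus
#' and ranks by the total number of non-synonymous substitution records
#' plus indel records, ties broken alphabetically.
#'
#' @param filtered Variant `data.frame` with effects classified.
#' @return `data.frame` with columns `locus`, `n_nonsyn_substitutions`,
#'   `n_indels`, sorted by rank.
#' @export
nominate_loci <- function(filtered) {
  keep <- filtered$region == "CDS" &
    !filtered$effect %in% c("synonymous", "noncoding") &
    filtered$type %in% c("substitution", "insertion", "deletion")
  v <- filtered[keep & !is.na(filtered$effect), , drop = FALSE]
  if (!nrow(v))
    return(data.frame(locus = character(), n_nonsyn_substitutions = integer(),
                      n_indels = integer(), stringsAsFactors = FALSE))
  tab <- do.call(rbind, lapply(split(v, v$locus), function(g) {
    data.frame(locus = g$locus[1],
               n_nonsyn_substitutions = sum(g$type == "substitution"),
               n_indels = sum(g$type %in% c("insertion", "deletion")),
               stringsAsFactors = FALSE)
  }))
  tot <- tab$n_nonsyn_substitutions + tab$n_indels
  tab <- tab[order(-tot, tab$locus), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Summarise the candidate funnel
#'
#' Bins a pattern-filtered variant set the way the screening funnel does:
#' noncoding variants (and the number of distinct noncoding regions they
#' fall in), coding loci, synonymous substitutions, non-synonymous
#' substitutions and coding indels. Every non-inversion variant lands in
#' exactly one bin.
#'
#' @param filtered Variant `data.frame` with effects classified.
#' @return Named list of counts.
#' @export
funnel_summary <- function(filtered) {
  v <- filtered[filtered$type != "inversion", , drop = FALSE]
  noncoding <- v$effect == "noncoding"
  coding <- !noncoding
  syn <- coding & v$effect == "synonymous"
  nonsyn_sub <- coding & v$type == "substitution" & v$effect != "synonymous"
  indel <- coding & v$type %in% c("insertion", "deletion") &
    v$effect != "synonymous"
  list(
    n_total = nrow(v),
    n_noncoding = sum(noncoding),
    n_noncoding_regions = length(unique(v$locus[noncoding])),
    n_coding_loci = length(unique(v$locus[coding])),
    n_synonymous = sum(syn),
    n_nonsyn_substitutions = sum(nonsyn_sub),
    n_indels = sum(indel)
  )
}

## ---------------------------------------------------------------------------
## TSV interchange (S1-style difference list)

#' Write / read a variant table with presence columns
#'
#' The normative interchange format: one row per variant with columns
#' `ref_start_1based`, `ref_end_1based`, `type`, `ref_allele`,
#' `alt_allele`, `locus`, `region`, `effect`, then one 0/1 presence column
#' per accession.
#'
#' @param matrix_ A `presence_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, the written `data.frame`.
#' @export
write_variant_table <- function(matrix_, path) {
  stopifnot(inherits(matrix_, "presence_matrix"))
  v <- matrix_$variants
  out <- data.frame(ref_start_1based = v$ref_start,
                    ref_end_1based = v$ref_end,
                    type = v$type, ref_allele = v$ref_allele,
                    alt_allele = v$alt_allele, locus = v$locus,
                    region = v$region, effect = v$effect,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(matrix_$present * 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(out)
}

#' @rdname write_variant_table
#' @param phenotypes Named phenotype vector for the accession columns.
#' @export
read_variant_table <- function(path, phenotypes) {
  d <- utils::read.delim(path, header = TRUE, na.strings = ".",
                         check.names = FALSE,
                         colClasses = NA, stringsAsFactors = FALSE)
  fixed <- c("ref_start_1based", "ref_end_1based", "type", "ref_allele",
             "alt_allele", "locus", "region", "effect")
  accs <- setdiff(names(d), fixed)
  v <- data.frame(ref_start = as.integer(d$ref_start_1based),
                  ref_end = as.integer(d$ref_end_1based),
                  type = d$type,
                  ref_allele = ifelse(is.na(d$ref_allele), "", d$ref_allele),
                  alt_allele = ifelse(is.na(d$alt_allele), "", d$alt_allele),
                  locus = d$locus, region = d$region, effect = d$effect,
                  stringsAsFactors = FALSE)
  present <- as.matrix(d[, accs, drop = FALSE]) == 1
  structure(list(variants = v, present = present,
                 phenotypes = phenotypes[accs]),
            class = "presence_matrix")
}
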