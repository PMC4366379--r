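#' Derive the protein product of an annotated CDS
#'
#' Translates a CDS under the plastid genetic code (translation table 11).
#' If the annotated start codon is disrupted, the first in-frame `ATG`
#' within `scan_codons` codons downstream is used instead
#' (`start_mode = "alternative_downstream"`), mirroring translation of an
#' allele whose original start was lost. If the annotated stop codon is
#' disrupted, translation reads through into downstream genomic sequence
#' until the next in-frame stop (`readthrough = TRUE`).
#'
#' @param genome An [annotated_genome()].
#' @param locus Name of an annotated CDS.
#' @param scan_codons Window (in codons) scanned for an alternative start.
#' @return Object of class `derived_protein`: list with `accession`,
#'   `locus`, `seq` (no stop symbol), `start_mode`, `readthrough`.
#' @export
derive_protein <- function(genome, locus, scan_codons = 60L) {
  cds <- cds_sequence(genome, locus)
  start_mode <- "annotated"
  if (substr(cds, 1L, 3L) != "ATG") {
    n_codon <- nchar(cds) %/% 3L
    found <- NA_integer_
    for (ci in seq_len(min(scan_codons, n_codon))) {
      if (substr(cds, 3L * ci - 2L, 3L * ci) == "ATG") { found <- ci; break }
    }
    if (is.na(found))
      stop("no alternative start: no in-frame ATG within ", scan_codons,
           " codons of CDS '", locus, "'")
    cds <- substr(cds, 3L * found - 2L, nchar(cds))
    start_mode <- "alternative_downstream"
  }
  aa <- translate_cds(cds, to_stop = FALSE)
  readthrough <- FALSE
  stop_at <- regexpr("\\*", aa)
  if (stop_at > 0L) {
    aa <- substr(aa, 1L, stop_at - 1L)
  } else {
    # annotated stop disrupted: extend into downstream genomic sequence
    readthrough <- TRUE
    cs <- cds_segments(genome, locus)
    last <- cs$segments[nrow(cs$segments), ]
    pos_after <- if (cs$strand == "+") last$end + 1L else last$start - 1L
    ext <- character()
    repeat {
      if (cs$strand == "+") {
        if (pos_after + 2L > nchar(genome$seq))
          stop("no downstream in-frame stop before sequence end for '",
               locus, "'")
        codon <- substr(genome$seq, pos_after, pos_after + 2L)
        pos_after <- pos_after + 3L
      } else {
        if (pos_after - 2L < 1L)
          stop("no downstream in-frame stop before sequence end for '",
               locus, "'")
        codon <- revcomp(substr(genome$seq, pos_after - 2L, pos_after))
        pos_after <- pos_after - 3L
      }
      if (is_stop_codon(codon)) break
      ext <- c(ext, unname(plastid_code()[codon]))
    }
    aa <- paste0(aa, paste(ext, collapse = ""))
  }
  structure(list(accession = genome$id, locus = locus, seq = aa,
                 start_mode = start_mode, readthrough = readthrough),
            class = "derived_protein")
}

protein_string <- function(x) {
  if (inherits(x, "derived_protein")) x$seq
  else if (is.character(x) && length(x) == 1L) x
  else stop("expected a derived_protein or a single protein string")
}

#' Progressive multiple alignment of derived proteins
#'
#' Centre-star progressive alignment: every sequence is aligned to the
#' first (reference) sequence by global Needleman-Wunsch
#' ([Biostrings::pairwiseAlignment()], BLOSUM62, affine gaps) and the
#' pairwise alignments are merged on the reference coordinate frame.
#' Insertions relative to the reference made by different sequences at the
#' same reference position share left-justified columns. Deterministic for
#' a fixed input order; terminal differences appear as gap columns.
#'
#' @param seqs Named list/vector of `derived_protein`s or plain protein
#'   strings; the first is the reference.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Object of class `protein_alignment`: character matrix (one row
#'   per sequence, one column per alignment position) with accession
#'   rownames.
#' @export
align_proteins <- function(seqs, gap_opening = 10, gap_extension = 0.5) {
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  nm <- names(seqs)
  if (is.null(nm))
    nm <- vapply(seqs, function(s)
      if (inherits(s, "derived_protein")) s$accession else NA_character_,
      character(1))
  if (anyNA(nm)) stop("sequences must be named")
  ss <- vapply(seqs, protein_string, character(1))
  if (any(!nzchar(ss))) stop("empty sequence in alignment input")
  ref <- ss[[1]]
  n <- nchar(ref)
  m <- length(ss)
  match_chars <- matrix("-", m, n)      # per ref position
  match_chars[1, ] <- strsplit(ref, "")[[1]]
  ins_str <- matrix("", m, n + 1L)      # insertions after ref pos 0..n
  for (j in 2:m) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ref), Biostrings::AAString(ss[[j]]),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension)
    gr <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    gs <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    rpos <- 0L
    for (c in seq_along(gr)) {
      if (gr[c] != "-") {
        rpos <- rpos + 1L
        if (gs[c] != "-") match_chars[j, rpos] <- gs[c]
      } else {
        ins_str[j, rpos + 1L] <- paste0(ins_str[j, rpos + 1L], gs[c])
      }
    }
  }
  ins_w <- apply(nchar(ins_str), 2, max)
  ncol_out <- n + sum(ins_w)
  aln <- matrix("-", m, ncol_out, dimnames = list(nm, NULL))
  col <- 0L
  for (i in 0:n) {
    w <- ins_w[i + 1L]
    if (w > 0L) {
      for (j in seq_len(m)) {
        s <- ins_str[j, i + 1L]
        if (nzchar(s))
          aln[j, col + seq_len(nchar(s))] <- strsplit(s, "")[[1]]
      }
      col <- col + w
    }
    if (i < n) {
      col <- col + 1L
      aln[, col] <- match_chars[, i + 1L]
    }
  }
  structure(aln, class = c("protein_alignment", class(aln)))
}

as_alignment <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is.character(aln)) {
    if (is.null(names(aln))) stop("alignment rows must be named")
    L <- unique(nchar(aln))
    if (length(L) != 1L) stop("aligned sequences differ in length")
    return(do.call(rbind, lapply(aln, function(s) strsplit(s, "")[[1]])))
  }
  stop("cannot interpret alignment input")
}

#' Variable-position table of a protein alignment
#'
#' Tabulates every difference from the reference row in alignment-column
#' coordinates, merging adjacent columns into one row when they share the
#' same difference kind and the same occurrence set of accessions (so a
#' two-residue replacement becomes e.g. `SD>IH`, and contiguous gap blocks
#' become single indel rows). Gap runs touching the alignment termini are
#' reported as terminal absence/addition.
#'
#' @param aln A `protein_alignment` (or named character vector of equal
#'   length aligned strings, or character matrix).
#' @param reference Row name of the reference accession (default: first
#'   row).
#' @return Object of class `variable_position_table`: `data.frame` with
#'   columns `start`, `end` (alignment columns), `kind` (`replacement`,
#'   `deletion`, `insertion`, `terminal_absence`, `terminal_addition`),
#'   `ref`, `alt`, `n_residues`, `accessions` (comma-separated); attributes
#'   `alignment_length`, `reference`, `accessions` (all non-reference
#'   rows).
#' @export
variable_position_table <- function(aln, reference = NULL) {
  aln <- as_alignment(aln)
  if (is.null(reference)) reference <- rownames(aln)[1]
  if (!reference %in% rownames(aln))
    stop("reference '", reference, "' not present in alignment")
  accs <- setdiff(rownames(aln), reference)
  L <- ncol(aln)
  rows <- list()
  if (length(accs) && L) {
    refrow <- aln[reference, ]
    # per-column cells: key = kind + participating accessions (+ content)
    cells <- vector("list", L)
    for (j in seq_len(L)) {
      rc <- unname(refrow[j])
      states <- list()
      for (a in accs) {
        ac <- unname(aln[a, j])
        if (ac == rc) next
        if (rc == "-" && ac != "-") {
          states[[a]] <- c(kind = "insertion", content = ac)
        } else if (rc != "-" && ac == "-") {
          states[[a]] <- c(kind = "deletion", content = rc)
        } else if (rc != "-" && ac != "-") {
          states[[a]] <- c(kind = "replacement", content = ac)
        }
      }
      if (!length(states)) next
      df <- data.frame(acc = names(states),
                       kind = vapply(states, `[[`, "", "kind"),
                       content = vapply(states, `[[`, "", "content"),
                       stringsAsFactors = FALSE)
      # partition: replacements/insertions split by alt residue;
      # deletions share the reference residue
      df$grp <- ifelse(df$kind == "deletion", df$kind,
                       paste(df$kind, df$content))
      cells[[j]] <- lapply(split(df, df$grp), function(g)
        list(kind = g$kind[1], accs = sort(g$acc),
             alt = g$content[1], col = j))
    }
    # merge adjacent cells with same kind + accession set
    open <- list()   # keyed by kind|accset
    close_row <- function(cell) {
      rows[[length(rows) + 1L]] <<- cell
    }
    for (j in seq_len(L)) {
      here <- cells[[j]]
      here_keys <- vapply(here, function(c.)
        paste(c.$kind, paste(c.$accs, collapse = ",")), character(1))
      # close open runs not continued
      for (k in names(open)) {
        if (!k %in% here_keys || open[[k]]$end != j - 1L) {
          close_row(open[[k]]); open[[k]] <- NULL
        }
      }
      for (i in seq_along(here)) {
        k <- here_keys[i]; c. <- here[[i]]
        if (!is.null(open[[k]]) && open[[k]]$end == j - 1L) {
          open[[k]]$end <- j
          open[[k]]$ref <- paste0(open[[k]]$ref,
                                  if (refrow[j] != "-") refrow[j] else "")
          open[[k]]$alt <- paste0(open[[k]]$alt,
                                  if (c.$kind != "deletion") c.$alt else "")
        } else {
          open[[k]] <- list(kind = c.$kind, accs = c.$accs,
                            start = j, end = j,
                            ref = if (refrow[j] != "-") refrow[j] else "",
                            alt = if (c.$kind != "deletion") c.$alt else "")
        }
      }
    }
    for (k in names(open)) close_row(open[[k]])
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    kind <- r$kind
    if (kind == "deletion" && (r$start == 1L || r$end == L))
      kind <- "terminal_absence"
    if (kind == "insertion" && (r$start == 1L || r$end == L))
      kind <- "terminal_addition"
    data.frame(start = r$start, end = r$end, kind = kind,
               ref = r$ref, alt = r$alt,
               n_residues = r$end - r$start + 1L,
               accessions = paste(r$accs, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(), kind = character(),
                      ref = character(), alt = character(),
                      n_residues = integer(), accessions = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$end, out$kind, out$alt, out$accessions), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, alignment_length = L, reference = reference,
            acc_set = accs,
            class = c("variable_position_table", class(out)))
}

#' Exclusive-difference filter
#'
#' Sub-table of rows whose occurrence set is exactly the target accession
#' set: present in every target accession and in no other accession.
#'
#' @param table A [variable_position_table()].
#' @param target,others Disjoint, non-empty accession sets; `others`
#'   defaults to all non-target accessions of the table.
#' @return The matching sub-table (same class and attributes).
#' @export
exclusive_differences <- function(table, target, others = NULL) {
  stopifnot(inherits(table, "variable_position_table"))
  acc_set <- attr(table, "acc_set")
  if (is.null(others)) others <- setdiff(acc_set, target)
  if (!length(target) || !length(others))
    stop("target and others must both be non-empty")
  if (length(intersect(target, others)))
    stop("target and others overlap: ",
         paste(intersect(target, others), collapse = ", "))
  occ <- strsplit(table$accessions, ",", fixed = TRUE)
  keep <- vapply(occ, function(o)
    all(target %in% o) && !any(others %in% o), logical(1))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("alignment_length", "reference", "acc_set")] <-
    attributes(table)[c("alignment_length", "reference", "acc_set")]
  class(out) <- class(table)
  out
}

#' Summaries of a variable-position (sub-)table
#'
#' Residue-level counts: replacements count every replaced residue
#' (a two-residue row counts 2), indel sizes are listed per row.
#'
#' @param table A [variable_position_table()].
#' @return List with `n_rows`, `n_variable_positions` (distinct replacement
#'   columns), `n_replaced_residues`, `deletion_sizes`, `insertion_sizes`,
#'   `n_indel_columns` (distinct alignment columns inside indel rows).
#' @export
variation_summary <- function(table) {
  repl <- table[table$kind == "replacement", , drop = FALSE]
  del <- table[table$kind %in% c("deletion", "terminal_absence"), ,
               drop = FALSE]
  ins <- table[table$kind %in% c("insertion", "terminal_addition"), ,
               drop = FALSE]
  indel <- rbind(del, ins)
  cols <- unique(unlist(mapply(seq, indel$start, indel$end,
                               SIMPLIFY = FALSE)))
  repl_cols <- unique(unlist(mapply(seq, repl$start, repl$end,
                                    SIMPLIFY = FALSE)))
  list(n_rows = nrow(table),
       n_variable_positions = length(repl_cols),
       n_replaced_residues = sum(repl$n_residues),
       deletion_sizes = del$n_residues,
       insertion_sizes = ins$n_residues,
       n_indel_columns = length(cols))
}

## ---------------------------------------------------------------------------
## Repeat and motif annotation

#' Find maximal tandem repeats
#'
#' Reports every maximal non-extendable tandem array with at least two
#' complete copies, for every unit length in `unit_len_range`. Arrays are
#' maximal runs of periodicity: overlapping arrays of different unit
#' lengths are all reported; phase-shifted sub-arrays of the same unit
#' length are not.
#'
#' @param seq Peptide (or DNA) string.
#' @param unit_len_range Integer vector `c(min, max)` of unit lengths.
#' @return `data.frame` with columns `start`, `end`, `unit`, `unit_length`,
#'   `copies`; `end - start + 1 == unit_length * copies`.
#' @export
find_tandem_repeats <- function(seq,
                                unit_len_range = c(1L,
                                                   nchar(seq) %/% 2L)) {
  n <- nchar(seq)
  lmin <- max(1L, unit_len_range[1])
  lmax <- min(n %/% 2L, unit_len_range[length(unit_len_range)])
  s <- strsplit(seq, "")[[1]]
  out <- list()
  for (L in seq_len(lmax)) {
    if (L < lmin) next
    eq <- s[seq_len(n - L)] == s[seq_len(n - L) + L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      run_len <- r$lengths[i]            # matched positions
      span <- run_len + L                # full periodic stretch
      copies <- span %/% L
      if (copies < 2L) next
      a <- starts[i]
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = a + copies * L - 1L,
        unit = paste(s[a:(a + L - 1L)], collapse = ""),
        unit_length = L, copies = copies, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(list(data.frame(start = integer(), end = integer(),
                                          unit = character(),
                                          unit_length = integer(),
                                          copies = integer(),
                                          stringsAsFactors = FALSE)), out))
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Longest homopolymer run of a residue
#'
#' @param seq Protein string.
#' @param residue Single amino-acid letter.
#' @return List with `length`, `start`, `end` (leftmost maximal run;
#'   `length = 0` and an empty span when the residue is absent).
#' @export
poly_run <- function(seq, residue) {
  stopifnot(nchar(residue) == 1L)
  s <- strsplit(seq, "")[[1]]
  r <- rle(s == residue)
  if (!any(r$values)) return(list(length = 0L, start = integer(),
                                  end = integer()))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]   # which.max -> leftmost tie
  list(length = r$lengths[best], start = starts[best], end = ends[best])
}

#' Scan for the CX2CX15CX2C zinc-finger motif
#'
#' Fixed-spacing cysteine motif `C-x(2)-C-x(15)-C-x(2)-C` (23 residues);
#' overlapping matches are all reported.
#'
#' @param seq Protein string.
#' @return `data.frame` with columns `start`, `end`.
#' @export
scan_zinc_finger <- function(seq) {
  m <- gregexpr("(?=C.{2}C.{15}C.{2}C)", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m), end = as.integer(m) + 22L)
}
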