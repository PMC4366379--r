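#' Annotated plastid genome
#'
#' Container for a single (typically plastid) genome sequence plus typed
#' features and assembly-gap spans. Coordinates are 1-based inclusive
#' throughout, matching GFF3 and the reporting frame of comparative tables.
#'
#' @param id Accession label, e.g. `"WL1238"`.
#' @param seq DNA sequence as a single character string over `A,C,G,T,N`.
#' @param features `data.frame` with columns `locus`, `kind` (one of
#'   `"CDS"`, `"intron"`, `"intergenic_spacer"`), `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `phase` (integer, `NA` for non-CDS). A CDS interrupted
#'   by introns is represented by several rows sharing one `locus`.
#' @param gaps `data.frame` with columns `start`, `end`: assembly gaps,
#'   which must consist entirely of `N` characters.
#' @param circular Logical; circular molecules are stored linearised at the
#'   reference origin.
#'
#' @return An object of class `annotated_genome`: a list with elements
#'   `id`, `seq`, `features`, `gaps`, `circular`.
#' @export
annotated_genome <- function(id, seq, features = empty_features(),
                             gaps = empty_gaps(), circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence for genome '", id, "'")
  if (grepl("[^ACGTN]", seq)) stop("sequence of '", id,
                                   "' contains non-ACGTN characters")
  features <- as_features(features)
  gaps <- as_gaps(gaps)
  bad <- features$start < 1L | features$end > n | features$start > features$end
  if (any(bad)) {
    stop("feature(s) outside sequence bounds in '", id, "': ",
         paste(unique(features$locus[bad]), collapse = ", "))
  }
  if (nrow(gaps)) {
    if (any(gaps$start < 1L | gaps$end > n | gaps$start > gaps$end))
      stop("gap span outside sequence bounds in '", id, "'")
    for (i in seq_len(nrow(gaps))) {
      span <- substr(seq, gaps$start[i], gaps$end[i])
      if (grepl("[^N]", span))
        stop("gap span [", gaps$start[i], ",", gaps$end[i],
             "] of '", id, "' contains non-N characters")
    }
  }
  structure(list(id = id, seq = seq, features = features, gaps = gaps,
                 circular = isTRUE(circular)),
            class = "annotated_genome")
}

empty_features <- function() {
  data.frame(locus = character(), kind = character(),
             start = integer(), end = integer(),
             strand = character(), phase = integer(),
             stringsAsFactors = FALSE)
}

empty_gaps <- function() {
  data.frame(start = integer(), end = integer())
}

feature_kinds <- c("CDS", "intron", "intergenic_spacer")

as_features <- function(features) {
  if (is.null(features) || nrow(features) == 0L) return(empty_features())
  req <- c("locus", "kind", "start", "end", "strand")
  if (!all(req %in% names(features)))
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  if (!"phase" %in% names(features)) features$phase <- NA_integer_
  features <- features[, c("locus", "kind", "start", "end", "strand", "phase")]
  features$locus <- as.character(features$locus)
  features$kind <- as.character(features$kind)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.character(features$strand)
  features$phase <- as.integer(features$phase)
  bad <- !features$kind %in% feature_kinds
  if (any(bad))
    stop("unsupported feature kind(s): ",
         paste(unique(features$kind[bad]), collapse = ", "))
  if (any(features$kind == "CDS" & !features$strand %in% c("+", "-")))
    stop("CDS feature(s) without annotated strand: ",
         paste(features$locus[features$kind == "CDS" &
                                !features$strand %in% c("+", "-")],
               collapse = ", "))
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  features
}

as_gaps <- function(gaps) {
  if (is.null(gaps) || nrow(gaps) == 0L) return(empty_gaps())
  stopifnot(all(c("start", "end") %in% names(gaps)))
  gaps <- data.frame(start = as.integer(gaps$start),
                     end = as.integer(gaps$end))
  gaps[order(gaps$start), , drop = FALSE]
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$id, ": ", nchar(x$seq), " bp",
      if (x$circular) " (circular, linearised)", "\n", sep = "")
  kinds <- table(factor(x$features$kind, levels = feature_kinds))
  cat("  features: ", paste(names(kinds), as.integer(kinds),
                            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  gaps: ", nrow(x$gaps), "\n", sep = "")
  invisible(x)
}

#' Read an annotated genome from FASTA + GFF3 (+ optional gap sidecar)
#'
#' The FASTA file must contain exactly one record. The GFF3 file is
#' restricted to feature types `CDS`, `intron` and `intergenic_spacer`,
#' with the feature name carried in a `locus` attribute. Gaps are read from
#' an optional two-column TSV (`start`, `end`, 1-based inclusive).
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param features_path Path to a GFF3 file, or `NULL` for no features.
#' @param gaps_path Optional path to the gap sidecar TSV.
#' @param circular Logical flag stored on the genome.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(fasta_path, features_path = NULL, gaps_path = NULL,
                        circular = FALSE) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dss) != 1L)
    stop("expected exactly one FASTA record in '", fasta_path, "', found ",
         length(dss))
  id <- sub("\\s.*$", "", names(dss)[1])
  seq <- as.character(dss[[1]])
  features <- empty_features()
  if (!is.null(features_path)) {
    gr <- rtracklayer::import(features_path, format = "gff3")
    if (length(gr)) {
      mc <- S4Vectors::mcols(gr)
      locus <- if ("locus" %in% names(mc)) as.character(mc$locus)
               else as.character(mc$ID)
      features <- data.frame(
        locus = locus,
        kind = as.character(mc$type),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        phase = if ("phase" %in% names(mc)) as.integer(mc$phase)
                else NA_integer_,
        stringsAsFactors = FALSE)
      features$strand[features$strand == "*"] <- "+"
    }
  }
  gaps <- empty_gaps()
  if (!is.null(gaps_path)) {
    gaps <- utils::read.delim(gaps_path, header = TRUE,
                              colClasses = "integer")
  }
  annotated_genome(id, seq, features, gaps, circular)
}

#' Write an annotated genome to FASTA + GFF3 (+ optional gap sidecar)
#'
#' Inverse of [read_genome()]: a genome written with `write_genome()` and
#' re-read compares equal field-by-field.
#'
#' @param genome An [annotated_genome()].
#' @param fasta_path,features_path,gaps_path Output paths; `features_path`
#'   and `gaps_path` may be `NULL` to skip.
#' @return Invisibly, `genome`.
#' @export
write_genome <- function(genome, fasta_path, features_path = NULL,
                         gaps_path = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  dss <- Biostrings::DNAStringSet(genome$seq)
  names(dss) <- genome$id
  Biostrings::writeXStringSet(dss, fasta_path)
  if (!is.null(features_path)) {
    f <- genome$features
    gr <- GenomicRanges::GRanges(
      seqnames = genome$id,
      ranges = IRanges::IRanges(start = f$start, end = f$end),
      strand = f$strand)
    S4Vectors::mcols(gr)$source <- "plastidcompat"
    S4Vectors::mcols(gr)$type <- f$kind
    S4Vectors::mcols(gr)$phase <- f$phase
    S4Vectors::mcols(gr)$locus <- f$locus
    rtracklayer::export(gr, features_path, format = "gff3")
  }
  if (!is.null(gaps_path)) {
    utils::write.table(genome$gaps, gaps_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(genome)
}

#' Gap-aware effective genome length
#'
#' Assembly gaps (runs of `N`) are counted not at their placeholder length
#' but at the length of the corresponding region of a gap-free reference
#' genome, located via exact flanking-anchor matches. This reproduces the
#' convention under which the length of unresolved regions is assumed equal
#' to that of the reference assembly.
#'
#' @param genome An [annotated_genome()] whose `gaps` spans are to be
#'   re-measured.
#' @param reference A gap-free [annotated_genome()] used to size the gaps.
#' @param flank Number of flanking bases used as anchors on each side.
#' @return Integer: sequence length with each gap span replaced by the
#'   length of its reference region. Equals `nchar(genome$seq)` when there
#'   are no gaps.
#' @export
effective_length <- function(genome, reference, flank = 30L) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(reference, "annotated_genome"))
  raw <- nchar(genome$seq)
  if (nrow(genome$gaps) == 0L) return(raw)
  refseq <- Biostrings::DNAString(reference$seq)
  total <- raw
  for (i in seq_len(nrow(genome$gaps))) {
    s <- genome$gaps$start[i]; e <- genome$gaps$end[i]
    if (s - flank < 1L || e + flank > raw)
      stop("unanchorable gap [", s, ",", e, "]: too close to sequence end")
    left <- substr(genome$seq, s - flank, s - 1L)
    right <- substr(genome$seq, e + 1L, e + flank)
    lm <- Biostrings::matchPattern(left, refseq)
    rm_ <- Biostrings::matchPattern(right, refseq)
    if (length(lm) != 1L || length(rm_) != 1L)
      stop("unanchorable gap [", s, ",", e, "]: flanking anchors not ",
           "unique in reference (", length(lm), " left, ", length(rm_),
           " right matches)")
    ref_len <- Biostrings::start(rm_)[1] - Biostrings::end(lm)[1] - 1L
    if (ref_len < 0L)
      stop("unanchorable gap [", s, ",", e, "]: anchors out of order ",
           "in reference")
    total <- total - (e - s + 1L) + ref_len
  }
  total
}
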