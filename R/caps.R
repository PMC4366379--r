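#' In-silico CAPS (cleaved amplified polymorphic sequence) prediction
#'
#' Predicts whether two amplicon alleles are distinguishable by digestion
#' with a restriction enzyme whose recognition site is given as an IUPAC
#' pattern (e.g. `"GCNGC"` for Fsp4HI). Matching is case-insensitive, on
#' both strands, with overlapping matches allowed. The marker is scored
#' polymorphic iff the two alleles' match-position sets differ.
#'
#' @param alleleA,alleleB Amplicon-scale DNA strings.
#' @param site IUPAC recognition pattern.
#' @param cut_offset Cut position within the site (bases 5' of the cut on
#'   the strand carrying the match). Defaults to the midpoint,
#'   `floor(nchar(site)/2)`.
#' @return A list with elements `polymorphic` (logical), `matches` (list of
#'   two `data.frame`s of forward-coordinate match starts and strands, one
#'   per allele), and `fragments` (list of two integer vectors of predicted
#'   digestion fragment lengths; each sums to the amplicon length).
#' @export
caps_predict <- function(alleleA, alleleB, site, cut_offset = NULL) {
  if (!nzchar(alleleA) || !nzchar(alleleB)) stop("empty allele sequence")
  if (missing(site) || !nzchar(site)) stop("empty recognition pattern")
  site <- toupper(site)
  if (is.null(cut_offset)) cut_offset <- nchar(site) %/% 2L
  a <- site_matches(alleleA, site)
  b <- site_matches(alleleB, site)
  list(
    polymorphic = !identical(a, b),
    matches = list(A = a, B = b),
    fragments = list(A = cut_fragments(nchar(alleleA), a, cut_offset,
                                       nchar(site)),
                     B = cut_fragments(nchar(alleleB), b, cut_offset,
                                       nchar(site)))
  )
}

# All matches of an IUPAC site on both strands, forward coordinates.
site_matches <- function(seq, site) {
  subj <- Biostrings::DNAString(toupper(seq))
  pat <- Biostrings::DNAString(site)
  fwd <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                  fixed = FALSE)
  res <- rbind(
    if (length(fwd)) data.frame(start = Biostrings::start(fwd),
                                strand = "+", stringsAsFactors = FALSE),
    if (length(rev)) data.frame(start = Biostrings::start(rev),
                                strand = "-", stringsAsFactors = FALSE))
  if (is.null(res)) res <- data.frame(start = integer(), strand = character(),
                                      stringsAsFactors = FALSE)
  res <- unique(res[order(res$start, res$strand), , drop = FALSE])
  rownames(res) <- NULL
  res
}

cut_fragments <- function(n, matches, cut_offset, site_len) {
  if (nrow(matches) == 0L) return(n)
  # a site matching both strands at the same start (degenerate
  # palindrome) is one physical double-strand cut
  dup <- matches$strand == "-" &
    matches$start %in% matches$start[matches$strand == "+"]
  matches <- matches[!dup, , drop = FALSE]
  # cut after `cut_offset` bases of the site on the matching strand;
  # mirrored for minus-strand matches.
  off <- ifelse(matches$strand == "+", cut_offset, site_len - cut_offset)
  cuts <- sort(unique(matches$start + off - 1L))
  cuts <- cuts[cuts >= 1L & cuts < n]
  diff(c(0L, cuts, n))
}
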