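# Independent brute-force oracles and shared fixtures for the test suite.

# cache for the (expensive) simulated screening panel + calls
.screen_cache <- new.env(parent = emptyenv())

get_screen_run <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.screen_cache[[key]])) {
    panel <- sim_genome_panel(pea_screen_config(seed))
    calls <- lapply(panel$genomes, function(g)
      align_and_call(panel$reference, g))
    .screen_cache[[key]] <- list(panel = panel, calls = calls)
  }
  .screen_cache[[key]]
}

random_protein <- function(n, alphabet = c("A", "B", "C", "D")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive tandem-repeat oracle: tests every (start, unit_len) pair,
# counting complete copies by direct unit comparison; keeps maximal runs
tandem_oracle <- function(seq, unit_len_range) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  out <- list()
  for (L in unit_len_range[1]:unit_len_range[2]) {
    if (L < 1L || L > n %/% 2L) next
    for (start in seq_len(n - 2L * L + 1L)) {
      # run start: periodicity must break just before `start`
      if (start > 1L && s[start - 1L] == s[start - 1L + L]) next
      unit <- paste(s[start:(start + L - 1L)], collapse = "")
      copies <- 1L
      while (start + (copies + 1L) * L - 1L <= n &&
             paste(s[(start + copies * L):(start + (copies + 1L) * L - 1L)],
                   collapse = "") == unit) {
        copies <- copies + 1L
      }
      if (copies >= 2L)
        out[[length(out) + 1L]] <- data.frame(
          start = start, end = start + copies * L - 1L, unit = unit,
          unit_length = L, copies = copies, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(list(data.frame(start = integer(),
                                          end = integer(),
                                          unit = character(),
                                          unit_length = integer(),
                                          copies = integer(),
                                          stringsAsFactors = FALSE)), out))
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# brute-force IUPAC site scan (independent of Biostrings)
iupac_regex <- function(site) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(toupper(site), "")[[1]]], collapse = "")
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTRYKMBVDHN", "TGCAYRMKVBHDN",
                            toupper(x)), "")[[1]]), collapse = "")
}

oracle_site_starts <- function(seq, site) {
  hits <- function(pat) {
    m <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), seq,
                  perl = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m)
  }
  sort(unique(c(hits(site), hits(revcomp_chr(site)))))
}

# tiny genome with one plus-strand CDS for effect-classification tests
one_cds_genome <- function(cds, flank5 = "GATTACA", flank3 = "TTGACCA",
                           id = "G", locus = "cdsA") {
  seq <- paste0(flank5, cds, flank3)
  annotated_genome(id, seq, data.frame(
    locus = locus, kind = "CDS", start = nchar(flank5) + 1L,
    end = nchar(flank5) + nchar(cds), strand = "+", phase = 0L))
}

sub_variant <- function(s, e, ref, alt)
  data.frame(ref_start = s, ref_end = e, type = "substitution",
             ref_allele = ref, alt_allele = alt, locus = NA_character_,
             region = NA_character_, effect = NA_character_,
             stringsAsFactors = FALSE)

indel_variant <- function(s, e, type, ref, alt)
  data.frame(ref_start = s, ref_end = e, type = type, ref_allele = ref,
             alt_allele = alt, locus = NA_character_,
             region = NA_character_, effect = NA_character_,
             stringsAsFactors = FALSE)
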