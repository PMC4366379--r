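#' RIL genotype tables
#'
#' A recombinant-inbred-line (RIL) genotype table is a character matrix of
#' lines x loci over `A` (one parental allele), `B` (the other) and `NA`
#' (missing; residual heterozygotes in an F6 population are coded
#' missing). Read/write as TSV with a `line` column followed by one column
#' per locus (`-` = missing).
#'
#' @param path TSV path.
#' @return A `ril_table` character matrix.
#' @export
read_ril_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(names(d)[1] == "line")
  g <- as.matrix(d[, -1, drop = FALSE])
  rownames(g) <- d$line
  g[g == "-"] <- NA_character_
  bad <- !is.na(g) & !g %in% c("A", "B")
  if (any(bad)) stop("RIL genotypes must be A, B or '-' (missing)")
  structure(g, class = c("ril_table", class(g)))
}

#' @rdname read_ril_table
#' @param table A `ril_table`.
#' @export
write_ril_table <- function(table, path) {
  g <- unclass(table)
  g[is.na(g)] <- "-"
  d <- data.frame(line = rownames(g), g, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

haldane_cM <- function(r) {
  ifelse(r >= 0.5, Inf, -50 * log(1 - 2 * r))
}

#' Two-point recombinant count with the Haldane-Waddington correction
#'
#' Counts lines with discordant genotypes at two loci (missing entries
#' excluded pairwise). The observed RIL recombinant fraction `R` is
#' converted to the per-meiosis recombination fraction by the
#' Haldane-Waddington relation for selfing RILs, `r = R / (2 - 2R)`, and
#' to a map distance by the Haldane map function.
#'
#' @param table A `ril_table`.
#' @param locusA,locusB Column names.
#' @return List with `n_recombinant`, `n_scored`, `R`, `r`, `cM`.
#' @export
recombinant_count <- function(table, locusA, locusB) {
  stopifnot(locusA %in% colnames(table), locusB %in% colnames(table))
  a <- table[, locusA]; b <- table[, locusB]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) stop("no commonly scored lines for ", locusA, " and ",
                    locusB)
  k <- sum(a[ok] != b[ok])
  R <- k / n
  r <- R / (2 - 2 * R)
  list(n_recombinant = k, n_scored = n, R = R, r = r, cM = haldane_cM(r))
}

#' Three-point marker ordering by double-recombinant minimisation
#'
#' For each candidate middle locus, counts lines whose genotype pattern
#' requires a double crossover under that order (the middle genotype
#' discordant with both flanking genotypes); returns the order minimising
#' apparent double recombinants. Ties are reported as ambiguous, never
#' silently broken.
#'
#' @param table A `ril_table`.
#' @param locusA,locusM,locusB Three distinct scored loci.
#' @return List with `order` (character(3)), `double_recombinants`,
#'   `ambiguous` (logical), `counts` (named per candidate middle).
#' @export
order_three <- function(table, locusA, locusM, locusB) {
  loci <- c(locusA, locusM, locusB)
  stopifnot(length(unique(loci)) == 3L, all(loci %in% colnames(table)))
  dbl <- function(mid) {
    fl <- setdiff(loci, mid)
    m <- table[, mid]; f1 <- table[, fl[1]]; f2 <- table[, fl[2]]
    ok <- !is.na(m) & !is.na(f1) & !is.na(f2)
    sum(m[ok] != f1[ok] & m[ok] != f2[ok])
  }
  counts <- vapply(loci, dbl, integer(1))
  best <- min(counts)
  mids <- names(counts)[counts == best]
  ambiguous <- length(mids) > 1L
  mid <- mids[1]
  list(order = c(setdiff(loci, mid)[1], mid, setdiff(loci, mid)[2]),
       double_recombinants = best, ambiguous = ambiguous, counts = counts)
}

#' Marker-phenotype cosegregation count
#'
#' Counts lines where the marker genotype equals a phenotype-assigned
#' genotype (e.g. the Scs1 state determined by progeny testing).
#'
#' @param table A `ril_table`.
#' @param locus Marker column name.
#' @param phenotype_genotypes Named character vector (line -> `A`/`B`).
#' @return List with `n_match`, `n_scored`.
#' @export
cosegregation <- function(table, locus, phenotype_genotypes) {
  stopifnot(locus %in% colnames(table))
  common <- intersect(rownames(table), names(phenotype_genotypes))
  g <- table[common, locus]
  p <- phenotype_genotypes[common]
  ok <- !is.na(g) & !is.na(p)
  if (!sum(ok)) stop("no commonly scored lines between marker and ",
                     "phenotype assignments")
  list(n_match = sum(g[ok] == p[ok]), n_scored = sum(ok))
}

#' Simulate an F6 RIL genotype table
#'
#' Stochastic mode draws each line's genotype at the first locus uniformly
#' and recombines each adjacent interval independently with the
#' RIL-observable probability `R = 2r / (1 + 2r)` (the fixation
#' probability of a recombinant chromosome under selfing at per-meiosis
#' recombination fraction `r`). Fixture mode (`patterns`) reproduces an
#' exact requested multiset of line genotype patterns.
#'
#' @param n_lines Number of lines (ignored in fixture mode).
#' @param loci Locus names.
#' @param r Per-interval per-meiosis recombination fractions, length
#'   `length(loci) - 1`, each in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param patterns Optional named integer vector: names are genotype
#'   strings over `A`/`B` (one character per locus), values are line
#'   counts; overrides stochastic mode.
#' @return List with `table` (a `ril_table`) and `r` (the truth values).
#' @export
sim_ril_population <- function(n_lines, loci, r, seed = 1L,
                               patterns = NULL) {
  if (!is.null(patterns)) {
    g <- do.call(rbind, strsplit(rep(names(patterns), patterns), ""))
    stopifnot(ncol(g) == length(loci))
  } else {
    if (any(r < 0 | r >= 0.5)) stop("per-meiosis r must lie in [0, 0.5)")
    stopifnot(length(r) == length(loci) - 1L)
    R <- 2 * r / (1 + 2 * r)
    g <- with_seed(seed, {
      first <- sample(c("A", "B"), n_lines, replace = TRUE)
      m <- matrix("", n_lines, length(loci))
      m[, 1] <- first
      for (j in seq_along(R)) {
        flip <- stats::runif(n_lines) < R[j]
        m[, j + 1L] <- ifelse(flip, chartr("AB", "BA", m[, j]), m[, j])
      }
      m
    })
  }
  dimnames(g) <- list(sprintf("RIL%04d", seq_len(nrow(g))), loci)
  list(table = structure(g, class = c("ril_table", class(g))),
       r = if (is.null(patterns)) r else NULL)
}
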