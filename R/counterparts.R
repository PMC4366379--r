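#' Nuclear multi-subunit-complex partners of a plastid locus
#'
#' Curated lookup of the nuclear-encoded subunits/partners known to act in
#' complex with the product of a plastid candidate locus: the ACCase
#' subunits for accD, sigma factors/CSP41/FeSOD3/PTK for rpoB, the TIC
#' import complex for ycf1; ycf2 has no known nuclear counterparts and
#' returns an empty list. The table is a static curated asset, not an
#' online lookup.
#'
#' @param locus Plastid locus name.
#' @param table Optional parsed partner table (named list); defaults to
#'   the bundled YAML asset.
#' @return List of partner descriptors, each with `complex`, `partners`,
#'   `keywords`; an empty list is a valid answer.
#' @export
complex_partners <- function(locus, table = NULL) {
  if (is.null(table)) table <- load_partner_table()
  if (!locus %in% names(table))
    stop("unknown plastid locus '", locus, "'; known: ",
         paste(names(table), collapse = ", "))
  out <- table[[locus]]
  if (is.null(out) || (is.list(out) && length(out) == 0L)) list() else out
}

load_partner_table <- function() {
  path <- system.file("extdata", "complex_partners.yaml",
                      package = "plastidcompat", mustWork = TRUE)
  yaml::read_yaml(path)
}

partner_keywords <- function(locus, table = NULL) {
  p <- complex_partners(locus, table)
  unique(unlist(lapply(p, `[[`, "keywords")))
}

#' Filter a syntenic gene-interval table
#'
#' Counts the annotated genes of a physical interval and selects those
#' whose product description matches any keyword (case-insensitive literal
#' substring). "Hypothetical protein" genes are counted by the same
#' literal-substring rule.
#'
#' @param table `data.frame` with columns `gene_id`, `description`,
#'   `chrom`, `start`, `end`.
#' @param interval Numeric `c(start, end)`; genes fully inside are
#'   counted.
#' @param keywords Character vector of keywords; may be empty.
#' @return List with `hits` (matching records, sorted by `start`),
#'   `n_genes`, `n_hypothetical`.
#' @export
interval_filter <- function(table, interval, keywords = character()) {
  req <- c("gene_id", "description", "chrom", "start", "end")
  stopifnot(all(req %in% names(table)))
  if (length(interval) != 2L || interval[1] > interval[2])
    stop("inverted or malformed interval [", interval[1], ", ",
         interval[2], "]")
  inside <- table$start >= interval[1] & table$end <= interval[2]
  recs <- table[inside, , drop = FALSE]
  recs <- recs[order(recs$start), , drop = FALSE]
  rownames(recs) <- NULL
  desc <- tolower(recs$description)
  hyp <- grepl("hypothetical protein", desc, fixed = TRUE)
  hit <- rep(FALSE, nrow(recs))
  for (k in keywords) hit <- hit | grepl(tolower(k), desc, fixed = TRUE)
  list(hits = recs[hit, , drop = FALSE],
       n_genes = nrow(recs),
       n_hypothetical = sum(hyp))
}

#' Synthetic syntenic gene-interval table
#'
#' Generates a gene-interval table emulating the annotated stretch of
#' Medicago truncatula chromosome 3 (NC_016409) between the
#' phosphoinositide phospholipase C and NSP2 genes that is syntenic to the
#' pea linkage-group III region harbouring Scs1: 166 annotated genes of
#' which 70 encode "hypothetical proteins", bracketed by the published
#' border genes, containing the biotin carboxyl carrier protein gene
#' (GeneID 11410363), the chloroplast lumen common family protein
#' (GeneID 11418002) and the holocarboxylase synthetase hcs2 candidate
#' (GeneID 11411288) 534,541 bp from the BCCP gene. Gene positions and the
#' remaining product descriptions are synthetic (the published supplement
#' is not machine-readable); only the named landmark genes, the counts and
#' the interval ends are faithful.
#'
#' @param seed Integer seed.
#' @param n_genes,n_hypothetical Panel composition.
#' @param interval Physical interval on the chromosome.
#' @return `data.frame` with columns `gene_id`, `description`, `chrom`,
#'   `start`, `end`.
#' @export
sim_gene_interval_table <- function(seed = 1L, n_genes = 166L,
                                    n_hypothetical = 70L,
                                    interval = c(22386715, 23539540)) {
  landmarks <- data.frame(
    gene_id = c("GeneID:11411269", "GeneID:11410363", "GeneID:11418002",
                "GeneID:11411288", "GeneID:11406790"),
    description = c("Phosphoinositide phospholipase C",
                    "Biotin carboxyl carrier protein of acetyl-CoA carboxylase",
                    "Chloroplast lumen common protein family",
                    "Holocarboxylase synthetase hcs2",
                    "Nodulation-signaling pathway 2 protein"),
    stringsAsFactors = FALSE)
  other_products <- c(
    "Pentatricopeptide repeat protein", "F-box family protein",
    "Leucine-rich repeat receptor-like kinase", "Cytochrome P450",
    "Serine/threonine protein kinase", "Zinc finger protein",
    "MYB transcription factor", "Ubiquitin-conjugating enzyme",
    "ABC transporter family protein", "Glycosyl hydrolase family protein",
    "Heat shock protein", "Ribosomal protein L7",
    "WD40 repeat-containing protein", "Aquaporin",
    "NBS-LRR disease resistance protein", "Sugar transporter",
    "Auxin response factor", "Calmodulin-binding protein",
    "Peroxidase", "GDSL esterase/lipase")
  n_other <- n_genes - n_hypothetical - nrow(landmarks)
  stopifnot(n_other >= 0L)
  descs <- c(landmarks$description,
             rep("hypothetical protein", n_hypothetical),
             with_seed(seed, sample(other_products, n_other,
                                    replace = TRUE)))
  ids <- c(landmarks$gene_id,
           sprintf("GeneID:SYN%05d", seq_len(n_genes - nrow(landmarks))))
  # positions: borders at the interval ends; the remaining genes spread
  # over the interior; BCCP and hcs2 separated by the published distance
  width <- 2000L
  span <- interval[2] - interval[1]
  bccp_start <- interval[1] + round(span * 0.55)
  hcs2_start <- bccp_start - 534541L
  interior <- with_seed(seed + 1L, sort(sample(
    seq(interval[1] + 5000L, interval[2] - 5000L - width, by = 50L),
    n_genes - nrow(landmarks))))
  starts <- c(interval[1], bccp_start, hcs2_start + 40000L, hcs2_start,
              interval[2] - width, interior)
  out <- data.frame(gene_id = ids, description = descs,
                    chrom = "NC_016409",
                    start = as.integer(starts),
                    end = as.integer(starts + width - 1L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
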