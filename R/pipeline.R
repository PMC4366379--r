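#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are
#' rejected. All stages run on bundled fixtures / seeded simulations by
#' default; paths can redirect individual stages to user files.
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("screen", "proteins", "counterparts", "linkage", "compat")`.
#' @param ril_path Optional RIL genotype TSV (default: the bundled
#'   88-line population).
#' @param outcomes_path Optional cross-outcome TSV (default: the bundled
#'   unambiguous cross set plus selfs).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       stages = c("screen", "proteins", "counterparts",
                                  "linkage", "compat"),
                       ril_path = NULL, outcomes_path = NULL) {
  known <- c("screen", "proteins", "counterparts", "linkage", "compat")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), stages = stages,
                 ril_path = ril_path, outcomes_path = outcomes_path),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with keys matching the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "stages", "ril_path", "outcomes_path")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full candidate-gene pipeline
#'
#' Orchestrates screening (seeded plastome panel, variant calling,
#' phenotype-pattern funnel, locus nomination), protein analysis
#' (variable-position tables and exclusive differences for the plastid
#' and nuclear candidates), counterpart search (syntenic interval
#' filtering), RIL linkage placement and the compatibility rule engine
#' (observed-cross concordance and determinant-state inference). Writes
#' one TSV per stage plus a Markdown summary and a log; reruns with the
#' same config and seed are byte-identical.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  if (file.exists(log_path)) file.remove(log_path)
  logf("plastidcompat ", as.character(utils::packageVersion(
    "plastidcompat")), " | seed=", config$seed,
    " | config md5=", unname(tools::md5sum(cfg_path)))
  report <- list()
  summary_lines <- c("# plastidcompat pipeline summary", "")

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    logf("stage ", name, ": start")
    res <- tryCatch(fun(), error = function(e) {
      logf("stage ", name, ": FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf("stage ", name, ": done")
    res
  }

  res <- run_stage("screen", function() {
    panel <- sim_genome_panel(pea_screen_config(config$seed))
    calls <- lapply(panel$genomes, function(g)
      align_and_call(panel$reference, g))
    pm <- build_presence_matrix(calls, panel$reference$id,
                                panel$phenotypes)
    filtered <- pattern_filter(pm)
    fun <- funnel_summary(filtered)
    cand <- nominate_loci(filtered)
    write_variant_table(pm, file.path(out_dir, "variants.tsv"))
    utils::write.table(cand, file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(presence = pm, filtered = filtered, funnel = fun,
         candidates = cand)
  })
  if (!is.null(res)) {
    report$screen <- res
    fun <- res$funnel
    summary_lines <- c(summary_lines, "## Candidate funnel", "",
      sprintf(paste0("%d pattern variants -> %d noncoding (in %d ",
                     "regions) dismissed -> %d synonymous dismissed -> ",
                     "%d non-synonymous substitutions + %d indels -> ",
                     "%d candidate loci (top: %s)"),
              fun$n_total, fun$n_noncoding, fun$n_noncoding_regions,
              fun$n_synonymous, fun$n_nonsyn_substitutions, fun$n_indels,
              nrow(res$candidates), res$candidates$locus[1]), "")
  }

  res <- run_stage("proteins", function() {
    t1 <- accd_variation_table()
    t2 <- bccp3_variation_table()
    e1 <- exclusive_differences(t1, c("VIR320", "L100"))
    e2 <- exclusive_differences(t2, c("VIR320", "L100"))
    utils::write.table(as.data.frame(t1),
                       file.path(out_dir, "accd_variable_positions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(t2),
                       file.path(out_dir, "bccp3_variable_positions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(accd = t1, bccp3 = t2, accd_exclusive = e1, bccp3_exclusive = e2)
  })
  if (!is.null(res)) {
    report$proteins <- res
    s1 <- variation_summary(res$accd_exclusive)
    s2 <- variation_summary(res$bccp3_exclusive)
    summary_lines <- c(summary_lines, "## Exclusive differences", "",
      sprintf(paste0("accD product: %d replaced residues, deletions of ",
                     "%s residues exclusive to VIR320+L100"),
              s1$n_replaced_residues,
              paste(sort(s1$deletion_sizes, decreasing = TRUE),
                    collapse = ", ")),
      sprintf("Bccp3 product: %d exclusive substitutions (positions %s)",
              nrow(res$bccp3_exclusive),
              paste(res$bccp3_exclusive$start, collapse = ", ")), "")
  }

  res <- run_stage("counterparts", function() {
    tab <- sim_gene_interval_table(config$seed)
    flt <- interval_filter(tab, c(22386715, 23539540),
                           partner_keywords("accD"))
    utils::write.table(flt$hits, file.path(out_dir,
                                           "counterpart_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    c(flt, list(table = tab))
  })
  if (!is.null(res)) {
    report$counterparts <- res
    summary_lines <- c(summary_lines, "## Nuclear counterpart search", "",
      sprintf(paste0("%d annotated genes in the syntenic interval (%d ",
                     "hypothetical proteins); ACCase-keyword hits: %s"),
              res$n_genes, res$n_hypothetical,
              paste(res$hits$description, collapse = "; ")), "")
  }

  res <- run_stage("linkage", function() {
    ril <- if (is.null(config$ril_path)) pea_ril_table()
           else read_ril_table(config$ril_path)
    rc <- recombinant_count(ril, "PhlC", "AJ832139")
    ord <- order_three(ril, "PhlC", "Bccp3", "AJ832139")
    cs <- cosegregation(ril, "Bccp3", stats::setNames(ril[, "Scs1"],
                                                      rownames(ril)))
    write_ril_table(ril, file.path(out_dir, "ril_genotypes.tsv"))
    list(ril = ril, flank = rc, order = ord, coseg = cs)
  })
  if (!is.null(res)) {
    report$linkage <- res
    summary_lines <- c(summary_lines, "## Linkage placement", "",
      sprintf(paste0("%d/%d recombinants between flanking markers; ",
                     "order %s with %d double recombinants; marker-",
                     "phenotype cosegregation %d/%d"),
              res$flank$n_recombinant, res$flank$n_scored,
              paste(res$order$order, collapse = " - "),
              res$order$double_recombinants,
              res$coseg$n_match, res$coseg$n_scored), "")
  }

  res <- run_stage("compat", function() {
    obs <- if (is.null(config$outcomes_path))
      pea_cross_outcomes(include_selfs = TRUE)
    else utils::read.delim(config$outcomes_path,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
    panel <- pea_determinant_panel()
    pred <- forward_panel(panel)
    key <- function(d) paste(d$cytoplasm_donor, d$nuclear_donor)
    m <- match(key(obs), key(pred))
    concord <- sum(obs$outcome == pred$outcome[m])
    inf <- infer_states(obs)
    utils::write.table(pred, file.path(out_dir, "predicted_crosses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(inf$identifiability,
                       file.path(out_dir, "inferred_states.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(panel = panel, predicted = pred, observed = obs,
         n_concordant = concord, n_observed = nrow(obs), inference = inf)
  })
  if (!is.null(res)) {
    report$compat <- res
    summary_lines <- c(summary_lines, "## Compatibility rule engine", "",
      sprintf(paste0("%d/%d observed cross outcomes reproduced; ",
                     "inference: %d consistent determinant assignment(s)"),
              res$n_concordant, res$n_observed,
              res$inference$n_solutions), "")
  }

  writeLines(summary_lines, file.path(out_dir, "summary.md"))
  logf("pipeline complete")
  invisible(report)
}
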