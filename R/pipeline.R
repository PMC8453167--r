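#' Run the full integrative pipeline
#'
#' Executes preprocess (probe filter, beta -> M, TMM), per-feature mixed
#' ANOVA with all three contrasts, family-wise BH adjustment and
#' significance calling, and the cross-layer integration steps (DM/DMDE,
#' target pairing, chains, mechanism-switch genes, methylation-expression
#' correlation, overlap summaries). Inputs may be in-memory objects or file
#' paths to the corresponding formats. The run never mutates its inputs and
#' is fully deterministic.
#'
#' @param design `study_design` or path to a design CSV
#' @param beta beta-value `omics_matrix` or TSV path
#' @param counts_mrna,counts_mirna count matrices or TSV paths
#' @param annotation `annotation_table` or TSV path
#' @param targets `target_db` or TSV path
#' @param out_dir output directory for TSVs and `run_summary.json`; `NULL`
#'   to skip writing
#' @param q_max FDR threshold
#' @param dbeta_min absolute delta-beta threshold for DMCs
#' @param fc_min fold-change display threshold
#' @param epsilon beta clipping bound for the M transform
#' @param trim_m,trim_a TMM trim fractions
#' @param promoter_regions region labels counted as promoter
#' @param evidence_min minimum target evidence level
#' @param require_same_direction passed to [detect_switch()]
#' @param seed recorded in the summary for provenance (the pipeline itself
#'   draws no random numbers)
#' @return (invisibly) list with all stage outputs and `summary`.
#' @export
run_pipeline <- function(design, beta, counts_mrna, counts_mirna,
                         annotation, targets, out_dir = NULL,
                         q_max = 0.05, dbeta_min = 0.1, fc_min = 2,
                         epsilon = 1e-6, trim_m = 0.30, trim_a = 0.05,
                         promoter_regions = PROMOTER_REGIONS_DEFAULT,
                         evidence_min = "high_confidence",
                         require_same_direction = FALSE, seed = NULL) {
  if (is.character(design)) design <- read_design(design)
  if (is.character(beta)) beta <- read_matrix(beta, "beta")
  if (is.character(counts_mrna))
    counts_mrna <- read_matrix(counts_mrna, "counts")
  if (is.character(counts_mirna))
    counts_mirna <- read_matrix(counts_mirna, "counts")
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(targets)) targets <- read_target_db(targets)

  # ---- preprocess ----------------------------------------------------
  filt <- filter_probes(beta, annotation)
  mval <- beta_to_m(filt$matrix, epsilon)
  tmm_mrna <- tmm_normalize(counts_mrna, trim_m, trim_a)
  tmm_mirna <- tmm_normalize(counts_mirna, trim_m, trim_a)
  log_mrna <- log2(unclass(tmm_mrna$normalized) + 0.5)
  log_mirna <- log2(unclass(tmm_mirna$normalized) + 0.5)

  # ---- mixed ANOVA ---------------------------------------------------
  res_meth <- run_all(mval, design)
  res_mrna <- run_all(log_mrna, design)
  res_mirna <- run_all(log_mirna, design)

  # ---- effects, BH per (omic, contrast) family, calling ---------------
  omics <- list(
    methylation = list(results = res_meth,
      effect = function(ct) delta_beta(filt$matrix, design, ct)),
    mrna = list(results = res_mrna,
      effect = function(ct) fold_change(tmm_mrna$normalized, design, ct)),
    mirna = list(results = res_mirna,
      effect = function(ct) fold_change(tmm_mirna$normalized, design, ct)))
  calls <- list()
  for (om in names(omics)) {
    per_ct <- lapply(CONTRASTS, function(ct) {
      fam <- omics[[om]]$results[omics[[om]]$results$contrast == ct, ]
      fam$q <- bh_adjust(fam$p)
      call_significant(fam, omics[[om]]$effect(ct), om,
                       q_max = q_max, dbeta_min = dbeta_min,
                       fc_min = fc_min)
    })
    names(per_ct) <- CONTRASTS
    calls[[om]] <- per_ct
  }
  call_table <- do.call(rbind, lapply(calls, function(x)
    do.call(rbind, x)))
  rownames(call_table) <- NULL

  # ---- integration ----------------------------------------------------
  pmap <- build_promoter_map(annotation, promoter_regions)
  dmc_all <- do.call(rbind, calls$methylation)
  dm <- dm_genes(dmc_all, pmap)
  dmde_mrna <- do.call(rbind, lapply(CONTRASTS, function(ct)
    select_dmde(dm[dm$contrast == ct, ], calls$mrna[[ct]])))
  dmde_mirna <- do.call(rbind, lapply(CONTRASTS, function(ct)
    select_dmde(dm[dm$contrast == ct, ], calls$mirna[[ct]])))
  pairs <- do.call(rbind, lapply(CONTRASTS, function(ct)
    match_targets(calls$mirna[[ct]], calls$mrna[[ct]], targets,
                  evidence_min)))
  chains <- build_chains(dmde_mirna, pairs)
  switches <- detect_switch(
    list(dmc = calls$methylation$AA, mrna = calls$mrna$AA,
         mirna = calls$mirna$AA),
    list(dmc = calls$methylation$EA, mrna = calls$mrna$EA,
         mirna = calls$mirna$EA),
    targets, pmap, evidence_min, require_same_direction)
  dmde_both <- rbind(dmde_mrna, dmde_mirna)
  correlations <- if (nrow(dmde_both) > 0)
    correlate_meth_expr(mval,
      rbind_expr(tmm_mrna$normalized, tmm_mirna$normalized),
      dmde_both, design, epsilon)
    else list(records = data.frame(), summary = data.frame())

  # ---- summaries -------------------------------------------------------
  grid2 <- lapply(stats::setNames(CONTRASTS, CONTRASTS), function(ct) {
    dmct <- dm[dm$contrast == ct, ]
    list(
      DMCs = sum(calls$methylation[[ct]]$significant),
      `DM genes` = length(unique(dmct$gene_id[dmct$gene_class == "mrna"])),
      `DM miRNAs` = length(unique(dmct$gene_id[dmct$gene_class == "mirna"])),
      `DE mRNAs` = sum(calls$mrna[[ct]]$significant),
      `DE miRNAs` = sum(calls$mirna[[ct]]$significant))
  })
  grid3 <- lapply(stats::setNames(CONTRASTS, CONTRASTS), function(ct) {
    dmct <- dm[dm$contrast == ct, ]
    dmm <- dmde_mrna[dmde_mrna$contrast == ct, ]
    dmi <- dmde_mirna[dmde_mirna$contrast == ct, ]
    prs <- pairs[pairs$contrast == ct, ]
    list(
      `DM genes` = length(unique(dmct$gene_id[dmct$gene_class == "mrna"])),
      `DMDE genes` = length(unique(dmm$gene_id)),
      `DMDE genes reciprocal` =
        length(unique(dmm$gene_id[dmm$gene_reciprocal])),
      `DM miRNAs` = length(unique(dmct$gene_id[dmct$gene_class == "mirna"])),
      `DMDE miRNAs` = length(unique(dmi$gene_id)),
      `DMDE miRNAs reciprocal` =
        length(unique(dmi$gene_id[dmi$gene_reciprocal])),
      `target pairs` = nrow(prs),
      `target pairs reciprocal` = sum(prs$reciprocal))
  })
  sig_ids <- function(tab) tab$feature_id[tab$significant]
  overlaps <- list(
    DMCs = overlap_summary(sig_ids(calls$methylation$AA),
                           sig_ids(calls$methylation$EA),
                           sig_ids(calls$methylation$ALL)),
    `DE mRNAs` = overlap_summary(sig_ids(calls$mrna$AA),
                                 sig_ids(calls$mrna$EA),
                                 sig_ids(calls$mrna$ALL)),
    `DE miRNAs` = overlap_summary(sig_ids(calls$mirna$AA),
                                  sig_ids(calls$mirna$EA),
                                  sig_ids(calls$mirna$ALL)),
    `DM genes` = overlap_summary(
      unique(dm$gene_id[dm$contrast == "AA" & dm$gene_class == "mrna"]),
      unique(dm$gene_id[dm$contrast == "EA" & dm$gene_class == "mrna"]),
      unique(dm$gene_id[dm$contrast == "ALL" & dm$gene_class == "mrna"])))
  summary <- list(
    thresholds = list(q_max = q_max, dbeta_min = dbeta_min,
                      fc_min = fc_min, epsilon = epsilon, trim_m = trim_m,
                      trim_a = trim_a,
                      promoter_regions = promoter_regions,
                      evidence_min = evidence_min,
                      require_same_direction = require_same_direction),
    seed = seed,
    probe_filter = list(tally = as.list(filt$tally),
                        removed_total = filt$removed_total,
                        kept = nrow(filt$matrix)),
    tmm = list(mrna_reference = tmm_mrna$reference_sample,
               mirna_reference = tmm_mirna$reference_sample),
    table2 = grid2, table3 = grid3, overlaps = overlaps,
    n_switch_genes = nrow(switches),
    correlation = correlations$summary)

  out <- list(calls = call_table, calls_by = calls,
              results = list(methylation = res_meth, mrna = res_mrna,
                             mirna = res_mirna),
              dm = dm, dmde_mrna = dmde_mrna, dmde_mirna = dmde_mirna,
              target_pairs = pairs, chains = chains, switches = switches,
              correlations = correlations, tmm = list(mrna = tmm_mrna,
                                                      mirna = tmm_mirna),
              filter = filt, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(call_table, file.path(out_dir, "calls.tsv"))
    write_results(res_meth, file.path(out_dir, "results_methylation.tsv"))
    write_results(res_mrna, file.path(out_dir, "results_mrna.tsv"))
    write_results(res_mirna, file.path(out_dir, "results_mirna.tsv"))
    write_results(dmde_both, file.path(out_dir, "dmde.tsv"))
    write_results(pairs, file.path(out_dir, "target_pairs.tsv"))
    write_results(chains, file.path(out_dir, "chains.tsv"))
    write_results(switches, file.path(out_dir, "switch_genes.tsv"))
    if (nrow(dmde_both) > 0)
      write_results(correlations$records,
                    file.path(out_dir, "correlations.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(out)
}

# stack two normalized expression matrices (disjoint feature sets)
rbind_expr <- function(a, b) {
  m <- rbind(unclass(a), unclass(b))
  omics_matrix(m, "normalized")
}

#' Render a Markdown report from a pipeline run directory
#'
#' @param run_dir directory written by [run_pipeline()]
#' @param path optional output path for the Markdown file
#' @return the report as a character string (invisibly when written)
#' @export
run_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  sj <- file.path(run_dir, "run_summary.json")
  if (!file.exists(sj)) ec_io_error(paste0("no run_summary.json in ", run_dir))
  s <- jsonlite::read_json(sj)
  grid_md <- function(grid) {
    cols <- names(grid[[1]])
    hdr <- paste0("| | ", paste(cols, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(cols) + 1), collapse = "|"),
                  "|")
    rows <- vapply(names(grid), function(ct)
      paste0("| ", ct, " | ",
             paste(unlist(grid[[ct]]), collapse = " | "), " |"), "")
    paste(c(hdr, sep, rows), collapse = "\n")
  }
  md <- paste0(
    "# Integrative analysis run report\n\n",
    "Thresholds: FDR < ", s$thresholds$q_max,
    ", |delta-beta| > ", s$thresholds$dbeta_min,
    ", promoter regions: ",
    paste(unlist(s$thresholds$promoter_regions), collapse = ", "), "\n\n",
    "Probes kept after QC filtering: ", s$probe_filter$kept,
    " (removed ", s$probe_filter$removed_total, ")\n\n",
    "## Significant molecules per contrast\n\n", grid_md(s$table2), "\n\n",
    "## Integration counts per contrast\n\n", grid_md(s$table3), "\n\n",
    "Mechanism-switch genes: ", s$n_switch_genes, "\n")
  if (!is.null(path)) {
    writeLines(md, path)
    return(invisible(md))
  }
  md
}
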