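#' Build a gene -> promoter-CpG map from the annotation
#'
#' @param annotation an `annotation_table`
#' @param promoter_regions region labels counted as promoter; default the
#'   Illumina promoter-proximal set TSS1500, TSS200, UTR5, FirstExon
#' @return A `promoter_map`: list with `map` (data.frame `gene_id`,
#'   `gene_class`, `probe_id`, `region`; genes with no promoter probe are
#'   absent) and `promoter_regions`.
#' @export
build_promoter_map <- function(annotation,
                               promoter_regions = PROMOTER_REGIONS_DEFAULT) {
  if (length(promoter_regions) == 0)
    ec_parameter_error("promoter_regions must be non-empty")
  bad <- setdiff(promoter_regions, REGIONS)
  if (length(bad) > 0)
    ec_value_error(paste0("unknown region label(s): ",
                          paste(bad, collapse = ", ")))
  map <- annotation$links[annotation$links$region %in% promoter_regions,
                          c("gene_id", "gene_class", "probe_id", "region")]
  rownames(map) <- NULL
  structure(list(map = map, promoter_regions = promoter_regions),
            class = "promoter_map")
}

#' Differentially methylated genes and miRNA genes per contrast
#'
#' A gene is DM for a contrast iff at least one of its promoter probes is a
#' significant DMC in that contrast. Output keeps one row per supporting
#' (contrast, gene, probe) as provenance.
#'
#' @param dmcs methylation differential calls (see [call_significant()]);
#'   may hold several contrasts
#' @param pmap a `promoter_map`
#' @return data.frame: `contrast`, `gene_id`, `gene_class`, `probe_id`,
#'   `dbeta`, `meth_direction` (`hyper`/`hypo`).
#' @export
dm_genes <- function(dmcs, pmap) {
  if (!all(dmcs$omic == "methylation"))
    ec_consistency_error("dm_genes expects methylation calls only")
  sig <- dmcs[dmcs$significant, , drop = FALSE]
  out <- merge(sig[, c("contrast", "feature_id", "effect")],
               pmap$map, by.x = "feature_id", by.y = "probe_id")
  out <- data.frame(contrast = out$contrast, gene_id = out$gene_id,
                    gene_class = out$gene_class, probe_id = out$feature_id,
                    dbeta = out$effect,
                    meth_direction = ifelse(out$effect > 0, "hyper", "hypo"))
  out <- out[order(out$contrast, out$gene_id, out$probe_id), ]
  rownames(out) <- NULL
  out
}

#' Select DMDE genes (differentially methylated AND expressed)
#'
#' Joins DM genes with expression calls of the matching gene class and
#' contrast. One record per (gene, supporting probe) where the gene is DE;
#' a probe is reciprocal when its methylation direction opposes the gene's
#' expression direction, and a gene is reciprocal when at least one of its
#' supporting probes is.
#'
#' @param dm output of [dm_genes()]
#' @param de expression differential calls (`mrna` or `mirna` omic)
#' @return data.frame of DMDE records: `contrast`, `gene_id`, `gene_class`,
#'   `probe_id`, `dbeta`, `meth_direction`, `expr_direction`, `reciprocal`,
#'   `gene_reciprocal`.
#' @export
select_dmde <- function(dm, de) {
  cls <- unique(de$omic)
  if (length(cls) != 1 || !cls %in% GENE_CLASSES)
    ec_consistency_error("de must be a single expression omic (mrna|mirna)")
  dm <- dm[dm$gene_class == cls, , drop = FALSE]
  de_sig <- de[de$significant, c("feature_id", "contrast", "direction")]
  out <- merge(dm, de_sig,
               by.x = c("gene_id", "contrast"),
               by.y = c("feature_id", "contrast"))
  if (nrow(out) == 0)
    return(data.frame(contrast = character(), gene_id = character(),
                      gene_class = character(), probe_id = character(),
                      dbeta = numeric(), meth_direction = character(),
                      expr_direction = character(), reciprocal = logical(),
                      gene_reciprocal = logical()))
  out$expr_direction <- out$direction
  out$direction <- NULL
  out$reciprocal <- (out$dbeta > 0 & out$expr_direction == "down") |
                    (out$dbeta < 0 & out$expr_direction == "up")
  key <- paste(out$contrast, out$gene_id)
  rec_by_gene <- tapply(out$reciprocal, key, any)
  out$gene_reciprocal <- unname(rec_by_gene[key])
  out <- out[order(out$contrast, out$gene_id, out$probe_id),
             c("contrast", "gene_id", "gene_class", "probe_id", "dbeta",
               "meth_direction", "expr_direction", "reciprocal",
               "gene_reciprocal")]
  rownames(out) <- NULL
  out
}

evidence_rank <- function(e) match(e, EVIDENCE_LEVELS)

#' Match DE miRNAs to DE target mRNAs through a target database
#'
#' Keeps (miRNA, gene) pairs where both are DE in the same contrast, the
#' pair is in the database at the requested evidence level or stronger,
#' and flags pairs whose directions oppose as reciprocal (non-reciprocal
#' pairs are retained with `reciprocal = FALSE`).
#'
#' @param de_mirna miRNA differential calls (one contrast)
#' @param de_mrna mRNA differential calls (same contrast)
#' @param db a `target_db`
#' @param evidence_min minimum evidence level (default `high_confidence`)
#' @return data.frame: `contrast`, `mirna_id`, `gene_id`, `evidence`,
#'   `mirna_direction`, `gene_direction`, `reciprocal`.
#' @export
match_targets <- function(de_mirna, de_mrna, db,
                          evidence_min = "high_confidence") {
  if (!evidence_min %in% EVIDENCE_LEVELS)
    ec_value_error(paste0("unknown evidence level: ", evidence_min))
  ctr <- unique(c(de_mirna$contrast, de_mrna$contrast))
  if (length(ctr) != 1)
    ec_consistency_error("both call tables must come from one contrast")
  mi <- de_mirna[de_mirna$significant, c("feature_id", "direction")]
  mr <- de_mrna[de_mrna$significant, c("feature_id", "direction")]
  keep <- db[evidence_rank(db$evidence) >= evidence_rank(evidence_min), ]
  out <- merge(merge(keep, mi, by.x = "mirna_id", by.y = "feature_id"),
               mr, by.x = "gene_id", by.y = "feature_id",
               suffixes = c("_mirna", "_gene"))
  if (nrow(out) == 0)
    return(data.frame(contrast = character(), mirna_id = character(),
                      gene_id = character(), evidence = character(),
                      mirna_direction = character(),
                      gene_direction = character(), reciprocal = logical()))
  out <- data.frame(contrast = ctr, mirna_id = out$mirna_id,
                    gene_id = out$gene_id, evidence = out$evidence,
                    mirna_direction = out$direction_mirna,
                    gene_direction = out$direction_gene)
  out$reciprocal <- out$mirna_direction != out$gene_direction
  out <- out[order(out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Assemble DNA-methylation -> miRNA -> mRNA regulatory chains
#'
#' One chain per (promoter probe, miRNA, target gene) where the probe
#' supports a reciprocal DMDE miRNA and the (miRNA, gene) pair is a
#' reciprocal DE target pair from the same contrast. By construction the
#' three directions alternate: hypo -> up -> down or hyper -> down -> up.
#'
#' @param dmde_mirna DMDE records of gene class `mirna` (see
#'   [select_dmde()]); only reciprocal rows are used
#' @param target_pairs output of [match_targets()]; only reciprocal rows
#'   are used
#' @return data.frame of chain records: `contrast`, `probe_id`, `mirna_id`,
#'   `gene_id`, `meth_direction`, `mirna_direction`, `target_direction`.
#' @export
build_chains <- function(dmde_mirna, target_pairs) {
  dm <- dmde_mirna[dmde_mirna$gene_class == "mirna" & dmde_mirna$reciprocal,
                   c("contrast", "gene_id", "probe_id", "meth_direction",
                     "expr_direction")]
  tp <- target_pairs[target_pairs$reciprocal,
                     c("contrast", "mirna_id", "gene_id", "gene_direction")]
  out <- merge(dm, tp, by.x = c("contrast", "gene_id"),
               by.y = c("contrast", "mirna_id"),
               suffixes = c("", "_target"))
  if (nrow(out) == 0)
    return(data.frame(contrast = character(), probe_id = character(),
                      mirna_id = character(), gene_id = character(),
                      meth_direction = character(),
                      mirna_direction = character(),
                      target_direction = character()))
  out <- data.frame(contrast = out$contrast, probe_id = out$probe_id,
                    mirna_id = out$gene_id, gene_id = out$gene_id_target,
                    meth_direction = out$meth_direction,
                    mirna_direction = out$expr_direction,
                    target_direction = out$gene_direction)
  stopifnot((out$meth_direction == "hyper") == (out$mirna_direction == "down"),
            out$mirna_direction != out$target_direction)
  out <- out[order(out$probe_id, out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Detect mechanism-switch genes between the racial strata
#'
#' A gene qualifies iff (a) it is DE in both AA and EA; (b) at least one
#' miRNA that is DE in AA but not in EA targets it (database evidence at
#' or above `evidence_min`) with direction opposing the gene's AA
#' expression; and (c) at least one promoter probe of the gene is a
#' reciprocal DMC in EA while the gene is not DM in AA at all. That is:
#' the epigenetic driver is miRNA-only in AA and promoter-methylation-only
#' in EA.
#'
#' @param calls_aa,calls_ea named lists with elements `dmc`, `mrna`,
#'   `mirna` holding the race's differential-call tables
#' @param db a `target_db`
#' @param pmap a `promoter_map`
#' @param evidence_min minimum target evidence level
#' @param require_same_direction if `TRUE`, additionally require the
#'   gene's DE direction to agree between the races
#' @return data.frame of switch records: `gene_id`, `gene_direction_aa`,
#'   `gene_direction_ea`, `aa_mirnas`, `ea_probes` (comma-joined),
#'   `n_aa_mirnas`, `n_ea_probes`.
#' @export
detect_switch <- function(calls_aa, calls_ea, db, pmap,
                          evidence_min = "high_confidence",
                          require_same_direction = FALSE) {
  empty <- data.frame(gene_id = character(), gene_direction_aa = character(),
                      gene_direction_ea = character(),
                      aa_mirnas = character(), ea_probes = character(),
                      n_aa_mirnas = integer(), n_ea_probes = integer())
  g_aa <- calls_aa$mrna[calls_aa$mrna$significant, ]
  g_ea <- calls_ea$mrna[calls_ea$mrna$significant, ]
  cand <- intersect(g_aa$feature_id, g_ea$feature_id)
  if (length(cand) == 0) return(empty)

  mi_aa <- calls_aa$mirna[calls_aa$mirna$significant, ]
  mi_ea_set <- calls_ea$mirna$feature_id[calls_ea$mirna$significant]
  dm_aa <- dm_genes(calls_aa$dmc, pmap)
  dm_ea <- dm_genes(calls_ea$dmc, pmap)
  keep_db <- db[evidence_rank(db$evidence) >= evidence_rank(evidence_min), ]

  rows <- lapply(sort(cand), function(g) {
    dir_aa <- g_aa$direction[g_aa$feature_id == g][1]
    dir_ea <- g_ea$direction[g_ea$feature_id == g][1]
    if (require_same_direction && dir_aa != dir_ea) return(NULL)
    # (b) AA-exclusive DE miRNA drivers with reciprocal target relation
    mir <- keep_db$mirna_id[keep_db$gene_id == g]
    mir <- mir[mir %in% mi_aa$feature_id & !(mir %in% mi_ea_set)]
    mir <- mir[mi_aa$direction[match(mir, mi_aa$feature_id)] != dir_aa]
    if (length(mir) == 0) return(NULL)
    # (c) EA-exclusive reciprocal promoter methylation
    if (g %in% dm_aa$gene_id) return(NULL)
    sup <- dm_ea[dm_ea$gene_id == g, , drop = FALSE]
    rec <- sup$probe_id[(sup$dbeta > 0 & dir_ea == "down") |
                        (sup$dbeta < 0 & dir_ea == "up")]
    if (length(rec) == 0) return(NULL)
    data.frame(gene_id = g, gene_direction_aa = dir_aa,
               gene_direction_ea = dir_ea,
               aa_mirnas = paste(sort(unique(mir)), collapse = ","),
               ea_probes = paste(sort(unique(rec)), collapse = ","),
               n_aa_mirnas = length(unique(mir)),
               n_ea_probes = length(unique(rec)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Correlate promoter methylation with expression over DMDE records
#'
#' For each DMDE record, the Pearson correlation between the supporting
#' probe's M-values and `log2(normalized expression + 0.5)` across all
#' samples of the record's stratum. A record with a constant vector gets
#' `r = NaN` and is excluded from the summary denominator.
#'
#' @param beta_or_m an `omics_matrix` of kind `beta` (converted
#'   internally) or `mvalue`
#' @param expr an `omics_matrix` of kind `normalized`
#' @param dmde DMDE records (see [select_dmde()])
#' @param design a `study_design`
#' @param epsilon clipping bound for the beta -> M conversion
#' @return list with `records` (dmde + `r` column) and `summary`
#'   (per-contrast `n`, `n_excluded`, `frac_gt_0.5` = fraction of usable
#'   records with `|r| > 0.5`).
#' @export
correlate_meth_expr <- function(beta_or_m, expr, dmde, design,
                                epsilon = 1e-6) {
  m <- if (identical(matrix_kind(beta_or_m), "beta"))
    beta_to_m(beta_or_m, epsilon) else beta_or_m
  e <- log2(unclass(expr) + 0.5)
  r <- vapply(seq_len(nrow(dmde)), function(i) {
    samples <- design_samples(design, dmde$contrast[i])
    if (length(samples) < 3)
      ec_consistency_error("need at least 3 samples per stratum")
    x <- unclass(m)[dmde$probe_id[i], samples]
    y <- e[dmde$gene_id[i], samples]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NaN)
    stats::cor(x, y)
  }, numeric(1))
  records <- data.frame(dmde, r = r)
  summ <- do.call(rbind, lapply(unique(dmde$contrast), function(ct) {
    ri <- r[dmde$contrast == ct]
    usable <- ri[is.finite(ri)]
    data.frame(contrast = ct, n = length(ri),
               n_excluded = sum(!is.finite(ri)),
               frac_gt_0.5 = if (length(usable) == 0) NaN else
                 mean(abs(usable) > 0.5))
  }))
  list(records = records, summary = summ)
}

#' Set-overlap summary between the AA and EA strata
#'
#' @param aa,ea,all character vectors of called identifiers (`all` optional)
#' @return list of counts: `aa_total`, `ea_total`, `overlap`, `aa_only`,
#'   `ea_only`, and `all_total` when `all` is given.
#' @export
overlap_summary <- function(aa, ea, all = NULL) {
  aa <- unique(aa); ea <- unique(ea)
  out <- list(aa_total = length(aa), ea_total = length(ea),
              overlap = length(intersect(aa, ea)),
              aa_only = length(setdiff(aa, ea)),
              ea_only = length(setdiff(ea, aa)))
  if (!is.null(all)) out$all_total <- length(unique(all))
  out
}
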