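test_that("promoter map restricts links to promoter regions", {
  ann <- make_toy_annotation()
  pmap <- build_promoter_map(ann)
  expect_setequal(pmap$map$gene_id, c("GENEA", "MIR589"))
  expect_equal(pmap$map$probe_id[pmap$map$gene_id == "GENEA"], "cg1")
  expect_equal(pmap$map$probe_id[pmap$map$gene_id == "MIR589"], "cg3")

  body_only <- build_promoter_map(ann, "Body")
  expect_equal(body_only$map$gene_id, "GENEA")
  expect_equal(body_only$map$probe_id, "cg2")
  expect_error(build_promoter_map(ann, character(0)),
               class = "epichain_parameter_error")

  # a probe in two genes' promoters appears under both
  ann2 <- annotation_table(
    data.frame(probe_id = "cg9", chrom = "chr1", pos = 1L, qc_flags = ""),
    data.frame(probe_id = c("cg9", "cg9"), gene_id = c("G1", "G2"),
               region = "TSS200", gene_class = "mrna"))
  expect_setequal(build_promoter_map(ann2)$map$gene_id, c("G1", "G2"))
})

test_that("DM genes require a significant promoter DMC in the contrast", {
  pmap <- build_promoter_map(make_toy_annotation())
  dmcs <- make_call_table(c("cg1", "cg2", "cg3"), "AA", "methylation",
                          q = c(0.01, 0.01, 0.5),
                          effect = c(0.2, -0.3, 0.2))
  dm <- dm_genes(dmcs, pmap)
  # cg2 is a Body probe, cg3 is not significant: only GENEA via cg1
  expect_equal(dm$gene_id, "GENEA")
  expect_equal(dm$probe_id, "cg1")
  expect_equal(dm$meth_direction, "hyper")
  empty <- dm_genes(dmcs[dmcs$q > 1, ], pmap)
  expect_equal(nrow(empty), 0)
})

test_that("a gene with opposite-sign promoter DMCs keeps both probes", {
  ann <- annotation_table(
    data.frame(probe_id = c("cgA", "cgB"), chrom = "chr1", pos = 1:2,
               qc_flags = ""),
    data.frame(probe_id = c("cgA", "cgB"), gene_id = "G1",
               region = c("TSS200", "TSS1500"), gene_class = "mrna"))
  dmcs <- make_call_table(c("cgA", "cgB"), "EA", "methylation",
                          q = c(0.01, 0.01), effect = c(0.2, -0.2))
  dm <- dm_genes(dmcs, build_promoter_map(ann))
  expect_equal(nrow(dm), 2)
  expect_equal(length(unique(dm$gene_id)), 1)
  # downstream: expression down makes only the hyper probe reciprocal,
  # and the gene counts as reciprocal because one probe is
  de <- make_call_table("G1", "EA", "mrna", q = 0.01, effect = 0.4)
  dmde <- select_dmde(dm, de)
  expect_equal(nrow(dmde), 2)
  expect_equal(sort(dmde$reciprocal), c(FALSE, TRUE))
  expect_true(all(dmde$gene_reciprocal))
})

test_that("DMDE selection applies the reciprocal sign rule", {
  pmap <- build_promoter_map(make_toy_annotation())
  dm <- dm_genes(make_call_table("cg1", "AA", "methylation", 0.01, 0.2),
                 pmap)
  up <- make_call_table("GENEA", "AA", "mrna", 0.01, 3.0)
  down <- make_call_table("GENEA", "AA", "mrna", 0.01, 0.3)
  expect_false(select_dmde(dm, up)$reciprocal)     # hyper + up
  expect_true(select_dmde(dm, down)$reciprocal)    # hyper + down
  # hypomethylated miRNA promoter with the miRNA up: reciprocal DMDE miRNA
  dm_mi <- dm_genes(make_call_table("cg3", "EA", "methylation", 0.01, -0.2),
                    pmap)
  mi_up <- make_call_table("MIR589", "EA", "mirna", 0.01, 2.5)
  rec <- select_dmde(dm_mi, mi_up)
  expect_true(rec$reciprocal)
  expect_equal(rec$gene_class, "mirna")
  # not DE: no DMDE record at all
  not_de <- make_call_table("GENEA", "AA", "mrna", 0.5, 3.0)
  expect_equal(nrow(select_dmde(dm, not_de)), 0)
})

test_that("target matching respects evidence levels and directions", {
  db <- target_db(data.frame(
    mirna_id = c("m1", "m1", "m2"), gene_id = c("g1", "g2", "g1"),
    evidence = c("experimental", "moderate", "high_confidence")))
  mi <- make_call_table(c("m1", "m2"), "AA", "mirna", q = c(0.01, 0.01),
                        effect = c(2.5, 0.4))
  mr <- make_call_table(c("g1", "g2"), "AA", "mrna", q = c(0.01, 0.01),
                        effect = c(0.3, 0.2))
  pairs <- match_targets(mi, mr, db)
  # m1-g2 drops out at moderate evidence; m2 (down) + g1 (down) is kept
  # but flagged non-reciprocal
  expect_equal(nrow(pairs), 2)
  p_m1 <- pairs[pairs$mirna_id == "m1", ]
  expect_true(p_m1$reciprocal)
  p_m2 <- pairs[pairs$mirna_id == "m2", ]
  expect_false(p_m2$reciprocal)
  # lowering the bar brings the moderate pair back
  expect_equal(nrow(match_targets(mi, mr, db, evidence_min = "moderate")), 3)
  expect_error(match_targets(mi, make_call_table("g1", "EA", "mrna", 0.01,
                                                 0.3), db),
               class = "epichain_consistency_error")
})

test_that("chains multiply probes by targets with alternating directions", {
  # 2 promoter probes on one miRNA x 3 reciprocal targets = 6 chains
  dmde_mi <- data.frame(contrast = "ALL", gene_id = "m1",
                        gene_class = "mirna", probe_id = c("cgA", "cgB"),
                        dbeta = -0.2, meth_direction = "hypo",
                        expr_direction = "up", reciprocal = TRUE,
                        gene_reciprocal = TRUE)
  pairs <- data.frame(contrast = "ALL", mirna_id = "m1",
                      gene_id = c("g1", "g2", "g3"),
                      evidence = "experimental", mirna_direction = "up",
                      gene_direction = "down", reciprocal = TRUE)
  ch <- build_chains(dmde_mi, pairs)
  expect_equal(nrow(ch), 6)
  expect_true(all(ch$meth_direction == "hypo" & ch$mirna_direction == "up" &
                  ch$target_direction == "down"))
  # no reciprocal DMDE miRNA: empty chain table
  none <- build_chains(dmde_mi[0, ], pairs)
  expect_equal(nrow(none), 0)
})

test_that("switch detection demands race-exclusive epi-drivers", {
  ann <- annotation_table(
    data.frame(probe_id = "cgZ", chrom = "chr1", pos = 1L, qc_flags = ""),
    data.frame(probe_id = "cgZ", gene_id = "G", region = "TSS200",
               gene_class = "mrna"))
  pmap <- build_promoter_map(ann)
  db <- target_db(data.frame(mirna_id = "mX", gene_id = "G",
                             evidence = "experimental"))
  dmc_null <- function(ct) make_call_table("cgZ", ct, "methylation", 0.9, 0)
  dmc_hit <- function(ct) make_call_table("cgZ", ct, "methylation", 0.01, 0.2)
  g_down <- function(ct, q = 0.01) make_call_table("G", ct, "mrna", q, 0.3)
  mi_up <- function(ct, q = 0.01) make_call_table("mX", ct, "mirna", q, 2.5)

  # G down in both races; mX up in AA only; cgZ hyper in EA only
  sw <- detect_switch(
    list(dmc = dmc_null("AA"), mrna = g_down("AA"), mirna = mi_up("AA")),
    list(dmc = dmc_hit("EA"), mrna = g_down("EA"), mirna = mi_up("EA", 0.9)),
    db, pmap)
  expect_equal(sw$gene_id, "G")
  expect_equal(sw$aa_mirnas, "mX")
  expect_equal(sw$ea_probes, "cgZ")

  # gene DE in AA only: excluded even with both epi-events present
  sw2 <- detect_switch(
    list(dmc = dmc_null("AA"), mrna = g_down("AA"), mirna = mi_up("AA")),
    list(dmc = dmc_hit("EA"), mrna = g_down("EA", 0.9),
         mirna = mi_up("EA", 0.9)),
    db, pmap)
  expect_equal(nrow(sw2), 0)

  # miRNA also DE in EA: no longer AA-exclusive, excluded
  sw3 <- detect_switch(
    list(dmc = dmc_null("AA"), mrna = g_down("AA"), mirna = mi_up("AA")),
    list(dmc = dmc_hit("EA"), mrna = g_down("EA"), mirna = mi_up("EA")),
    db, pmap)
  expect_equal(nrow(sw3), 0)

  # gene also DM in AA: methylation no longer EA-exclusive, excluded
  sw4 <- detect_switch(
    list(dmc = dmc_hit("AA"), mrna = g_down("AA"), mirna = mi_up("AA")),
    list(dmc = dmc_hit("EA"), mrna = g_down("EA"), mirna = mi_up("EA", 0.9)),
    db, pmap)
  expect_equal(nrow(sw4), 0)
})

test_that("methylation-expression correlation matches the sum formula", {
  design <- make_design(2, 2)
  aa_samples <- design$sample_id[design$race == "AA"]
  # probe M {1,2,3,4} against expression chosen so log2(e + 0.5) = {4,3,2,1}
  mvals <- matrix(0, 1, 8, dimnames = list("cg1", design$sample_id))
  mvals[1, aa_samples] <- c(1, 2, 3, 4)
  expr <- matrix(1, 1, 8, dimnames = list("GENEA", design$sample_id))
  expr[1, aa_samples] <- 2^c(4, 3, 2, 1) - 0.5
  dmde <- data.frame(contrast = "AA", gene_id = "GENEA",
                     gene_class = "mrna", probe_id = "cg1", dbeta = 0.2,
                     meth_direction = "hyper", expr_direction = "down",
                     reciprocal = TRUE, gene_reciprocal = TRUE)
  out <- correlate_meth_expr(omics_matrix(mvals, "mvalue"),
                             omics_matrix(expr, "normalized"), dmde, design)
  expect_equal(out$records$r, -1)
  expect_equal(out$summary$frac_gt_0.5, 1)

  # random pairs agree with the textbook sum formula to 1e-12
  set.seed(41)
  design20 <- make_design(5, 5)  # 20 samples in the pooled stratum
  x <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("cgA", "cgB"), design20$sample_id))
  e <- matrix(abs(rnorm(40, 10)), 2, 20,
              dimnames = list(c("gA", "gB"), design20$sample_id))
  dm2 <- data.frame(contrast = "ALL", gene_id = c("gA", "gB"),
                    gene_class = "mrna", probe_id = c("cgA", "cgB"),
                    dbeta = 0.2, meth_direction = "hyper",
                    expr_direction = "down", reciprocal = TRUE,
                    gene_reciprocal = TRUE)
  out2 <- correlate_meth_expr(omics_matrix(x, "mvalue"),
                              omics_matrix(e, "normalized"), dm2, design20)
  sum_formula <- function(a, b) {
    n <- length(a)
    (n * sum(a * b) - sum(a) * sum(b)) /
      sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  }
  expect_equal(out2$records$r[1],
               sum_formula(x["cgA", ], log2(e["gA", ] + 0.5)),
               tolerance = 1e-12)
  expect_equal(out2$records$r[2],
               sum_formula(x["cgB", ], log2(e["gB", ] + 0.5)),
               tolerance = 1e-12)

  # constant expression: r = NaN, excluded from the denominator
  const <- e; const["gA", ] <- 7
  out3 <- correlate_meth_expr(omics_matrix(x, "mvalue"),
                              omics_matrix(const, "normalized"), dm2,
                              design20)
  expect_true(is.nan(out3$records$r[1]))
  expect_equal(out3$summary$n_excluded, 1)
})

test_that("overlap summaries are plain set algebra that reconciles", {
  ov <- overlap_summary(c("a", "b"), c("b", "c"))
  expect_equal(ov$overlap, 1)
  expect_equal(ov$aa_only, 1)
  expect_equal(ov$ea_only, 1)
  expect_equal(ov$aa_only + ov$overlap, ov$aa_total)
  expect_equal(overlap_summary("x", "y")$overlap, 0)
})
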