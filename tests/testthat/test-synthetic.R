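small_cfg <- function(...) {
  sim_config(n_cpg = 600, n_mirna = 80, n_mrna = 400,
             frac_dmc_shared = 0.05, frac_dmc_aa_only = 0.02,
             frac_dmc_ea_only = 0.06,
             frac_de_mrna_shared = 0.08, frac_de_mrna_aa_only = 0.03,
             frac_de_mrna_ea_only = 0.03,
             frac_de_mirna_shared = 0.06, frac_de_mirna_aa_only = 0.08,
             frac_de_mirna_ea_only = 0.03,
             n_dmde = 2, n_chains = 2, n_switch = 2, seed = 3, ...)
}

test_that("simulated cohorts are valid and reproducible by seed", {
  sim <- simulate_cohort(small_cfg())
  expect_s3_class(sim$design, "study_design")
  b <- unclass(sim$beta)
  expect_true(all(b > 0 & b < 1))
  cm <- unclass(sim$counts_mrna)
  expect_true(all(cm >= 0 & cm == round(cm)))
  expect_equal(matrix_kind(sim$counts_mirna), "counts")
  # emitted files pass the io validators untouched
  dir <- tempfile(); write_cohort(sim, dir)
  expect_s3_class(read_design(file.path(dir, "design.csv")), "study_design")
  expect_s3_class(read_annotation(file.path(dir, "annotation.tsv")),
                  "annotation_table")
  expect_s3_class(read_target_db(file.path(dir, "targets.tsv")), "target_db")
  back <- read_matrix(file.path(dir, "beta.tsv"), "beta")
  expect_identical(unclass(back), unclass(sim$beta), ignore_attr = TRUE)

  sim2 <- simulate_cohort(small_cfg())
  expect_identical(unclass(sim$beta), unclass(sim2$beta))
  expect_identical(unclass(sim$counts_mrna), unclass(sim2$counts_mrna))
  expect_identical(sim$target_db, sim2$target_db)

  # every ground-truth identifier exists in the generated objects
  expect_true(all(sim$truth$dmc$ALL %in% rownames(sim$beta)))
  expect_true(all(sim$truth$switch$gene_id %in% rownames(sim$counts_mrna)))
  expect_true(all(sim$truth$chains$mirna_id %in%
                    rownames(sim$counts_mirna)))
  expect_true(all(sim$truth$dmde_mrna$probe_id %in%
                    sim$annotation$probes$probe_id))
})

test_that("infeasible configurations are rejected before generation", {
  expect_error(sim_config(n_aa = 1), class = "epichain_parameter_error")
  expect_error(sim_config(frac_dmc_shared = 0.9, frac_dmc_ea_only = 0.3),
               class = "epichain_parameter_error")
  # structural counts larger than the planted pools
  expect_error(sim_config(n_cpg = 100, frac_dmc_shared = 0.02,
                          n_dmde = 10, n_chains = 5),
               class = "epichain_parameter_error")
  expect_error(sim_config(dbeta_effect = 0.95),
               class = "epichain_parameter_error")
})

test_that("planted delta-beta is calibrated to the requested effect", {
  cfg <- sim_config(n_cpg = 5000, n_mirna = 10, n_mrna = 50,
                    frac_dmc_shared = 0.4, frac_dmc_aa_only = 0,
                    frac_dmc_ea_only = 0, frac_de_mrna_shared = 0,
                    frac_de_mrna_aa_only = 0, frac_de_mrna_ea_only = 0,
                    frac_de_mirna_shared = 0, frac_de_mirna_aa_only = 0,
                    frac_de_mirna_ea_only = 0, dbeta_effect = 0.25,
                    patient_sd = 0.5, beta_logit_sd = 0.8,
                    n_dmde = 0, n_chains = 0, n_switch = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  planted <- sim$truth$dmc$ALL           # 2000 planted shared sites
  expect_gte(length(planted), 2000)
  signs <- sim$truth$effects$cpg_sign[planted]
  db <- delta_beta(sim$beta, sim$design, "ALL")[planted]
  expect_equal(mean(db * signs), 0.25, tolerance = 0.02)
})

test_that("DMC sensitivity grows with the planted effect size", {
  sens <- vapply(c(0.1, 0.3), function(eff) {
    cfg <- sim_config(n_cpg = 1000, n_mirna = 10, n_mrna = 50,
                      frac_dmc_shared = 0.2, frac_de_mrna_shared = 0,
                      frac_de_mrna_aa_only = 0, frac_de_mrna_ea_only = 0,
                      frac_de_mirna_shared = 0, frac_de_mirna_aa_only = 0,
                      frac_de_mirna_ea_only = 0, frac_dmc_aa_only = 0,
                      frac_dmc_ea_only = 0, dbeta_effect = eff,
                      n_dmde = 0, n_chains = 0, n_switch = 0, seed = 17)
    sim <- simulate_cohort(cfg)
    res <- run_all(beta_to_m(sim$beta), sim$design)
    fam <- res[res$contrast == "ALL", ]
    fam$q <- bh_adjust(fam$p)
    calls <- call_significant(fam, delta_beta(sim$beta, sim$design, "ALL"),
                              "methylation")
    truth_eval(calls$feature_id[calls$significant],
               sim$truth$dmc$ALL)$sensitivity
  }, numeric(1))
  expect_gt(sens[2], sens[1])
})

test_that("truth_eval computes FDP and sensitivity arithmetic exactly", {
  truth <- paste0("t", 1:9)
  perfect <- truth_eval(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdp, 0)
  empty <- truth_eval(character(0), truth)
  expect_equal(empty$sensitivity, 0)
  expect_equal(empty$fdp, 0)        # max(1, .) guard
  decoy <- truth_eval(c(truth, "decoy"), truth)
  expect_equal(decoy$fdp, 0.1)
  expect_equal(decoy$sensitivity, 1)
  expect_true(is.nan(truth_eval("x", character(0))$sensitivity))
})

test_that("Gaussian expression generator plants the requested effects", {
  g <- simulate_expression_matrix(n_features = 400, frac_de = 0.25,
                                  effect = 2, seed = 4)
  expect_equal(length(g$de_features), 100)
  expect_equal(dim(g$matrix), c(400, 32))
  res <- run_all(g$matrix, g$design)
  fam <- res[res$contrast == "ALL", ]
  est <- setNames(fam$estimate, fam$feature_id)
  planted <- g$de_features
  expect_equal(mean(est[planted] * g$signs[planted]), 2, tolerance = 0.1)
  g2 <- simulate_expression_matrix(n_features = 400, frac_de = 0.25,
                                   effect = 2, seed = 4)
  expect_identical(g$matrix, g2$matrix)
})
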