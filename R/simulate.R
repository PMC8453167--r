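# Fully linked synthetic cohort generator. Every planted event is recorded
# in a ground-truth object so downstream calls can be scored exactly.

#' Build and validate a simulation configuration
#'
#' Defaults describe a paired two-race cohort of 8 AA + 8 EA patients with
#' EA-dominant differential methylation and AA-dominant differential miRNA
#' expression, the asymmetry this pipeline is designed to resolve. Planted
#' beta effects are calibrated on the logit scale to achieve the requested
#' expected delta-beta at each probe's baseline; counts are negative
#' binomial with log-normal library sizes.
#'
#' @param n_aa,n_ea patients per race (>= 2)
#' @param n_cpg,n_mirna,n_mrna feature counts
#' @param frac_dmc_shared,frac_dmc_aa_only,frac_dmc_ea_only fractions of
#'   CpGs carrying a disease effect in both / only AA / only EA
#' @param frac_de_mrna_shared,frac_de_mrna_aa_only,frac_de_mrna_ea_only
#'   analogous fractions for mRNAs
#' @param frac_de_mirna_shared,frac_de_mirna_aa_only,frac_de_mirna_ea_only
#'   analogous fractions for miRNAs
#' @param dbeta_effect planted expected delta-beta at affected CpGs
#' @param lfc_effect planted log2 fold change at DE features
#' @param beta_logit_sd residual noise sd on the log2-logit (M) scale
#' @param patient_sd patient random-effect sd (M scale for methylation,
#'   log2 scale for counts)
#' @param nb_dispersion negative-binomial dispersion (1/size)
#' @param mean_depth mean library size
#' @param lib_sd sd of log library size (log-normal library sizes)
#' @param frac_flagged fraction of CpGs given QC flags / sex chromosomes
#' @param n_dmde planted reciprocal DMDE mRNA genes per stratum category
#'   (shared, AA-only, EA-only)
#' @param n_chains planted methylation -> miRNA -> mRNA chains (shared)
#' @param targets_per_chain DE target genes per chain miRNA
#' @param n_switch planted mechanism-switch genes (DE in both races,
#'   AA-only miRNA driver, EA-only promoter DMC)
#' @param decoy_factor decoy target-DB pairs per planted pair
#' @param multi_probe_promoters if `TRUE`, each DMDE gene gets a second,
#'   non-reciprocal promoter probe (exercises the per-probe provenance
#'   rule)
#' @param seed RNG seed
#' @return validated `sim_config` list
#' @export
sim_config <- function(n_aa = 8, n_ea = 8,
                       n_cpg = 5000, n_mirna = 600, n_mrna = 4000,
                       frac_dmc_shared = 0.04, frac_dmc_aa_only = 0.01,
                       frac_dmc_ea_only = 0.05,
                       frac_de_mrna_shared = 0.05,
                       frac_de_mrna_aa_only = 0.02,
                       frac_de_mrna_ea_only = 0.02,
                       frac_de_mirna_shared = 0.01,
                       frac_de_mirna_aa_only = 0.03,
                       frac_de_mirna_ea_only = 0.005,
                       dbeta_effect = 0.25, lfc_effect = 1.5,
                       beta_logit_sd = 0.8, patient_sd = 0.5,
                       nb_dispersion = 0.1, mean_depth = 1e6, lib_sd = 0.3,
                       frac_flagged = 0.02,
                       n_dmde = 5, n_chains = 3, targets_per_chain = 2,
                       n_switch = 3, decoy_factor = 5,
                       multi_probe_promoters = FALSE, seed = 1) {
  cfg <- as.list(environment())
  if (n_aa < 2 || n_ea < 2)
    ec_parameter_error("need at least 2 patients per race")
  fr <- c(frac_dmc_shared, frac_dmc_aa_only, frac_dmc_ea_only,
          frac_de_mrna_shared, frac_de_mrna_aa_only, frac_de_mrna_ea_only,
          frac_de_mirna_shared, frac_de_mirna_aa_only, frac_de_mirna_ea_only,
          frac_flagged)
  if (any(fr < 0) || any(fr > 1))
    ec_parameter_error("planted fractions must lie in [0, 1]")
  if (frac_dmc_shared + frac_dmc_aa_only + frac_dmc_ea_only +
      frac_flagged > 1)
    ec_parameter_error("CpG fractions sum above 1")
  if (frac_de_mrna_shared + frac_de_mrna_aa_only + frac_de_mrna_ea_only > 1 ||
      frac_de_mirna_shared + frac_de_mirna_aa_only + frac_de_mirna_ea_only > 1)
    ec_parameter_error("DE fractions sum above 1")
  if (dbeta_effect < 0 || dbeta_effect > 0.85)
    ec_parameter_error("dbeta_effect must lie in [0, 0.85]")
  if (beta_logit_sd < 0 || patient_sd < 0 || nb_dispersion <= 0 ||
      mean_depth <= 0)
    ec_parameter_error("noise/depth parameters out of range")
  if (any(c(n_dmde, n_chains, targets_per_chain, n_switch,
            decoy_factor) < 0))
    ec_parameter_error("structural counts must be >= 0")

  k <- if (multi_probe_promoters) 2L else 1L
  pools <- sim_pools(cfg)
  need_sh <- n_dmde * k + n_chains
  need_aa <- n_dmde * k
  need_ea <- n_dmde * k + n_switch
  if (pools$cpg_sh < need_sh || pools$cpg_aa < need_aa ||
      pools$cpg_ea < need_ea)
    ec_parameter_error("planted DMC pools too small for structural CpGs")
  if (pools$mrna_sh < n_dmde + n_chains * targets_per_chain + n_switch ||
      pools$mrna_aa < n_dmde || pools$mrna_ea < n_dmde)
    ec_parameter_error("planted DE mRNA pools too small for structure")
  if (pools$mirna_sh < n_chains || pools$mirna_aa < n_switch)
    ec_parameter_error("planted DE miRNA pools too small for structure")
  class(cfg) <- "sim_config"
  cfg
}

sim_pools <- function(cfg) {
  list(cpg_sh = round(cfg$frac_dmc_shared * cfg$n_cpg),
       cpg_aa = round(cfg$frac_dmc_aa_only * cfg$n_cpg),
       cpg_ea = round(cfg$frac_dmc_ea_only * cfg$n_cpg),
       cpg_flag = round(cfg$frac_flagged * cfg$n_cpg),
       mrna_sh = round(cfg$frac_de_mrna_shared * cfg$n_mrna),
       mrna_aa = round(cfg$frac_de_mrna_aa_only * cfg$n_mrna),
       mrna_ea = round(cfg$frac_de_mrna_ea_only * cfg$n_mrna),
       mirna_sh = round(cfg$frac_de_mirna_shared * cfg$n_mirna),
       mirna_aa = round(cfg$frac_de_mirna_aa_only * cfg$n_mirna),
       mirna_ea = round(cfg$frac_de_mirna_ea_only * cfg$n_mirna))
}

# expected value of inv_logit2(m + sd*Z), Z standard normal, tabulated on a
# grid; used to calibrate logit shifts so planted sites hit the requested
# expected delta-beta despite the nonlinearity of the inverse logit.
smooth_logit_table <- function(sd, lo = -18, hi = 18, by = 0.02) {
  mg <- seq(lo, hi, by = by)
  if (sd == 0) return(list(m = mg, g = inv_logit2(mg)))
  z <- stats::qnorm((seq_len(256) - 0.5) / 256) * sd
  g <- vapply(mg, function(m) mean(inv_logit2(m + z)), numeric(1))
  list(m = mg, g = g)
}

# logit shift delta such that E[beta(m0 + delta)] - E[beta(m0)] = target
calibrated_shift <- function(m0, target, tab) {
  g0 <- stats::approx(tab$m, tab$g, xout = m0)$y
  m1 <- stats::approx(tab$g, tab$m, xout = g0 + target)$y
  if (anyNA(m1))
    ec_parameter_error("planted delta-beta infeasible at a baseline")
  m1 - m0
}

nb_counts_matrix <- function(n_feat, ids, design, lfc, mask, cfg) {
  n_samp <- nrow(design)
  w <- stats::rlnorm(n_feat, 0, 1.5)
  p <- w / sum(w)
  lib <- round(cfg$mean_depth * exp(stats::rnorm(n_samp, 0, cfg$lib_sd)))
  pat <- match(design$patient_id, unique(design$patient_id))
  tau <- matrix(stats::rnorm(n_feat * length(unique(pat))),
                nrow = n_feat)
  log_mu <- outer(log2(p), log2(lib), "+") +
    cfg$patient_sd * tau[, pat, drop = FALSE] + lfc * mask
  mu <- 2^log_mu
  cnt <- matrix(stats::rnbinom(n_feat * n_samp, mu = mu,
                               size = 1 / cfg$nb_dispersion),
                nrow = n_feat, dimnames = list(ids, design$sample_id))
  omics_matrix(cnt, "counts")
}

# features x samples indicator of where a planted effect applies:
# rows grouped in blocks (shared, aa-only, ea-only), columns by design
effect_mask <- function(n_feat, blocks, design) {
  mask <- matrix(0, n_feat, nrow(design))
  tum <- design$tissue == "tumor"
  aa <- design$race == "AA"
  if (length(blocks$sh) > 0) mask[blocks$sh, tum] <- 1
  if (length(blocks$aa) > 0) mask[blocks$aa, tum & aa] <- 1
  if (length(blocks$ea) > 0) mask[blocks$ea, tum & !aa] <- 1
  mask
}

#' Simulate a fully linked multi-omics cohort with ground truth
#'
#' Generates a paired tumor/adjacent design for `n_aa` + `n_ea` patients, a
#' beta-value matrix (logit-normal with patient random effects and
#' calibrated planted disease shifts), negative-binomial miRNA and mRNA
#' count matrices with planted log2 fold changes, a CpG annotation whose
#' promoter links realize the planted DMDE genes, chains, and switch
#' genes, and a target database holding the planted reciprocal pairs plus
#' decoys. The same seed reproduces the cohort bit-exactly.
#'
#' @param config a `sim_config`
#' @return list with `design`, `beta`, `counts_mirna`, `counts_mrna`,
#'   `annotation`, `target_db`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- if (inherits(config, "sim_config")) config else
    do.call(sim_config, config)
  set.seed(cfg$seed)
  pools <- sim_pools(cfg)
  k <- if (cfg$multi_probe_promoters) 2L else 1L

  pid <- c(sprintf("aa%02d", seq_len(cfg$n_aa)),
           sprintf("ea%02d", seq_len(cfg$n_ea)))
  design <- study_design(data.frame(
    sample_id = c(paste0(pid, "_T"), paste0(pid, "_N")),
    patient_id = rep(pid, 2),
    race = rep(rep(RACES, c(cfg$n_aa, cfg$n_ea)), 2),
    tissue = rep(TISSUES, each = length(pid))))

  cpg_ids <- sprintf("cg%06d", seq_len(cfg$n_cpg))
  mrna_ids <- sprintf("gene%05d", seq_len(cfg$n_mrna))
  mirna_ids <- sprintf("mir%04d", seq_len(cfg$n_mirna))

  # ---- block layout -------------------------------------------------
  blk <- function(n) if (n == 0) integer(0) else seq_len(n)
  cpg_sh <- blk(pools$cpg_sh)
  cpg_aa <- pools$cpg_sh + blk(pools$cpg_aa)
  cpg_ea <- pools$cpg_sh + pools$cpg_aa + blk(pools$cpg_ea)
  n_planted_cpg <- pools$cpg_sh + pools$cpg_aa + pools$cpg_ea
  cpg_flag <- n_planted_cpg + blk(pools$cpg_flag)

  mrna_sh <- blk(pools$mrna_sh)
  mrna_aa <- pools$mrna_sh + blk(pools$mrna_aa)
  mrna_ea <- pools$mrna_sh + pools$mrna_aa + blk(pools$mrna_ea)
  mirna_sh <- blk(pools$mirna_sh)
  mirna_aa <- pools$mirna_sh + blk(pools$mirna_aa)
  mirna_ea <- pools$mirna_sh + pools$mirna_aa + blk(pools$mirna_ea)

  # structural reservations within the planted blocks
  res <- function(pool, n, offset = 0) pool[offset + blk(n)]
  dmde_probe_sh <- res(cpg_sh, cfg$n_dmde * k)
  chain_probe <- res(cpg_sh, cfg$n_chains, cfg$n_dmde * k)
  dmde_probe_aa <- res(cpg_aa, cfg$n_dmde * k)
  dmde_probe_ea <- res(cpg_ea, cfg$n_dmde * k)
  switch_probe <- res(cpg_ea, cfg$n_switch, cfg$n_dmde * k)

  dmde_gene_sh <- res(mrna_sh, cfg$n_dmde)
  chain_gene <- res(mrna_sh, cfg$n_chains * cfg$targets_per_chain,
                    cfg$n_dmde)
  switch_gene <- res(mrna_sh, cfg$n_switch,
                     cfg$n_dmde + cfg$n_chains * cfg$targets_per_chain)
  dmde_gene_aa <- res(mrna_aa, cfg$n_dmde)
  dmde_gene_ea <- res(mrna_ea, cfg$n_dmde)
  chain_mirna <- res(mirna_sh, cfg$n_chains)
  switch_mirna <- res(mirna_aa, cfg$n_switch)

  # ---- signs --------------------------------------------------------
  mrna_de <- c(mrna_sh, mrna_aa, mrna_ea)
  mirna_de <- c(mirna_sh, mirna_aa, mirna_ea)
  mrna_sign <- integer(cfg$n_mrna)
  mrna_sign[mrna_de] <- sample(c(-1L, 1L), length(mrna_de), replace = TRUE)
  mirna_sign <- integer(cfg$n_mirna)
  mirna_sign[mirna_de] <- sample(c(-1L, 1L), length(mirna_de),
                                 replace = TRUE)
  # chain targets oppose their chain miRNA; switch drivers oppose their gene
  if (cfg$n_chains > 0 && cfg$targets_per_chain > 0)
    mrna_sign[chain_gene] <-
      -rep(mirna_sign[chain_mirna], each = cfg$targets_per_chain)
  if (cfg$n_switch > 0)
    mirna_sign[switch_mirna] <- -mrna_sign[switch_gene]

  cpg_planted <- c(cpg_sh, cpg_aa, cpg_ea)
  cpg_sign <- integer(cfg$n_cpg)
  cpg_sign[cpg_planted] <- sample(c(-1L, 1L), length(cpg_planted),
                                  replace = TRUE)
  # reciprocal promoter probes oppose their gene's expression direction;
  # with multi-probe promoters the second probe agrees (non-reciprocal)
  set_probe_signs <- function(probes, genes_sign) {
    if (length(probes) == 0) return()
    first <- probes[seq(1, length(probes), by = k)]
    cpg_sign[first] <<- -genes_sign
    if (k == 2) cpg_sign[probes[seq(2, length(probes), by = k)]] <<-
        genes_sign
  }
  set_probe_signs(dmde_probe_sh, mrna_sign[dmde_gene_sh])
  set_probe_signs(dmde_probe_aa, mrna_sign[dmde_gene_aa])
  set_probe_signs(dmde_probe_ea, mrna_sign[dmde_gene_ea])
  if (cfg$n_chains > 0) cpg_sign[chain_probe] <- -mirna_sign[chain_mirna]
  if (cfg$n_switch > 0) cpg_sign[switch_probe] <- -mrna_sign[switch_gene]

  # ---- beta matrix --------------------------------------------------
  beta0 <- stats::runif(cfg$n_cpg, 0.05, 0.95)
  hyper <- cpg_sign > 0
  hypo <- cpg_sign < 0
  beta0[hyper] <- stats::runif(sum(hyper), 0.05, 0.93 - cfg$dbeta_effect)
  beta0[hypo] <- stats::runif(sum(hypo), cfg$dbeta_effect + 0.07, 0.95)
  m0 <- log2(beta0 / (1 - beta0))
  total_sd <- sqrt(cfg$patient_sd^2 + cfg$beta_logit_sd^2)
  tab <- smooth_logit_table(total_sd)
  delta <- numeric(cfg$n_cpg)
  if (length(cpg_planted) > 0)
    delta[cpg_planted] <- calibrated_shift(
      m0[cpg_planted], cpg_sign[cpg_planted] * cfg$dbeta_effect, tab)
  bmask <- effect_mask(cfg$n_cpg,
                       list(sh = cpg_sh, aa = cpg_aa, ea = cpg_ea), design)
  pat <- match(design$patient_id, unique(design$patient_id))
  tau <- matrix(stats::rnorm(cfg$n_cpg * length(pid)), nrow = cfg$n_cpg)
  M <- m0 + cfg$patient_sd * tau[, pat, drop = FALSE] + delta * bmask +
    cfg$beta_logit_sd * matrix(stats::rnorm(cfg$n_cpg * nrow(design)),
                               nrow = cfg$n_cpg)
  beta <- inv_logit2(M)
  dimnames(beta) <- list(cpg_ids, design$sample_id)
  beta <- omics_matrix(beta, "beta")

  # ---- count matrices -----------------------------------------------
  mrna_lfc <- mrna_sign * cfg$lfc_effect
  mirna_lfc <- mirna_sign * cfg$lfc_effect
  counts_mrna <- nb_counts_matrix(cfg$n_mrna, mrna_ids, design, mrna_lfc,
    effect_mask(cfg$n_mrna, list(sh = mrna_sh, aa = mrna_aa, ea = mrna_ea),
                design), cfg)
  counts_mirna <- nb_counts_matrix(cfg$n_mirna, mirna_ids, design,
    mirna_lfc,
    effect_mask(cfg$n_mirna,
                list(sh = mirna_sh, aa = mirna_aa, ea = mirna_ea), design),
    cfg)

  # ---- annotation ----------------------------------------------------
  chrom <- sample(paste0("chr", 1:22), cfg$n_cpg, replace = TRUE)
  qc <- character(cfg$n_cpg)
  if (pools$cpg_flag > 0) {
    fl <- QC_FLAGS[(seq_along(cpg_flag) - 1L) %% length(QC_FLAGS) + 1L]
    qc[cpg_flag] <- fl
    chrom[cpg_flag][fl == "sex_chrom"] <-
      sample(c("chrX", "chrY"), sum(fl == "sex_chrom"), replace = TRUE)
  }
  probes <- data.frame(probe_id = cpg_ids, chrom = chrom,
                       pos = sample.int(1e8, cfg$n_cpg, replace = TRUE),
                       qc_flags = qc)
  promoter_of <- function(probes_idx, gene_idx, ids, cls, each = 1L) {
    if (length(probes_idx) == 0) return(NULL)
    data.frame(probe_id = cpg_ids[probes_idx],
               gene_id = rep(ids[gene_idx], each = each),
               region = sample(c("TSS200", "TSS1500"), length(probes_idx),
                               replace = TRUE),
               gene_class = cls)
  }
  links <- rbind(
    promoter_of(dmde_probe_sh, dmde_gene_sh, mrna_ids, "mrna", k),
    promoter_of(dmde_probe_aa, dmde_gene_aa, mrna_ids, "mrna", k),
    promoter_of(dmde_probe_ea, dmde_gene_ea, mrna_ids, "mrna", k),
    promoter_of(chain_probe, chain_mirna, mirna_ids, "mirna"),
    promoter_of(switch_probe, switch_gene, mrna_ids, "mrna"))
  # background links sit outside promoters so planted promoter structure
  # alone defines DM-gene truth
  structural <- c(dmde_probe_sh, dmde_probe_aa, dmde_probe_ea,
                  chain_probe, switch_probe)
  bg <- setdiff(seq_len(cfg$n_cpg), structural)
  bg <- bg[stats::runif(length(bg)) < 0.8]
  if (length(bg) > 0)
    links <- rbind(links, data.frame(
      probe_id = cpg_ids[bg],
      gene_id = sample(mrna_ids, length(bg), replace = TRUE),
      region = sample(c("Body", "UTR3"), length(bg), replace = TRUE),
      gene_class = "mrna"))
  annotation <- annotation_table(probes, links %||% data.frame())

  # ---- target database -----------------------------------------------
  planted_pairs <- rbind(
    if (cfg$n_chains > 0 && cfg$targets_per_chain > 0)
      data.frame(mirna_id = rep(mirna_ids[chain_mirna],
                                each = cfg$targets_per_chain),
                 gene_id = mrna_ids[chain_gene], evidence = "experimental"),
    if (cfg$n_switch > 0)
      data.frame(mirna_id = mirna_ids[switch_mirna],
                 gene_id = mrna_ids[switch_gene],
                 evidence = "experimental"))
  n_planted <- if (is.null(planted_pairs)) 0L else nrow(planted_pairs)
  null_mirna <- setdiff(seq_len(cfg$n_mirna), mirna_de)
  null_mrna <- setdiff(seq_len(cfg$n_mrna), mrna_de)
  n_decoy <- cfg$decoy_factor * n_planted
  decoys <- NULL
  if (n_decoy > 0 && length(null_mirna) > 0 && length(null_mrna) > 0) {
    dm <- sample(null_mirna, n_decoy, replace = TRUE)
    dg <- sample(null_mrna, n_decoy, replace = TRUE)
    keep <- !duplicated(paste(dm, dg))
    decoys <- data.frame(mirna_id = mirna_ids[dm[keep]],
                         gene_id = mrna_ids[dg[keep]],
                         evidence = sample(EVIDENCE_LEVELS, sum(keep),
                                           replace = TRUE))
  }
  db <- target_db(rbind(planted_pairs, decoys) %||%
                    data.frame(mirna_id = character(),
                               gene_id = character(),
                               evidence = character()))

  # ---- ground truth ---------------------------------------------------
  strat_sets <- function(ids, sh, aa, ea)
    list(AA = ids[c(sh, aa)], EA = ids[c(sh, ea)], ALL = ids[c(sh, aa, ea)])
  dmde_truth <- function(genes, probes, stratum) {
    if (length(genes) == 0) return(NULL)
    data.frame(gene_id = mrna_ids[rep(genes, each = k)],
               probe_id = cpg_ids[probes],
               stratum = stratum,
               reciprocal = rep(c(TRUE, FALSE)[seq_len(k)],
                                length(genes)))
  }
  truth <- list(
    dmc = strat_sets(cpg_ids, cpg_sh, cpg_aa, cpg_ea),
    de_mrna = strat_sets(mrna_ids, mrna_sh, mrna_aa, mrna_ea),
    de_mirna = strat_sets(mirna_ids, mirna_sh, mirna_aa, mirna_ea),
    dmde_mrna = rbind(dmde_truth(dmde_gene_sh, dmde_probe_sh, "shared"),
                      dmde_truth(dmde_gene_aa, dmde_probe_aa, "aa_only"),
                      dmde_truth(dmde_gene_ea, dmde_probe_ea, "ea_only")),
    chains = if (cfg$n_chains > 0 && cfg$targets_per_chain > 0)
      data.frame(probe_id = rep(cpg_ids[chain_probe],
                                each = cfg$targets_per_chain),
                 mirna_id = rep(mirna_ids[chain_mirna],
                                each = cfg$targets_per_chain),
                 gene_id = mrna_ids[chain_gene]),
    switch = if (cfg$n_switch > 0)
      data.frame(gene_id = mrna_ids[switch_gene],
                 mirna_id = mirna_ids[switch_mirna],
                 probe_id = cpg_ids[switch_probe]),
    effects = list(dbeta = cfg$dbeta_effect, lfc = cfg$lfc_effect,
                   cpg_sign = stats::setNames(cpg_sign, cpg_ids),
                   mrna_sign = stats::setNames(mrna_sign, mrna_ids),
                   mirna_sign = stats::setNames(mirna_sign, mirna_ids)))

  structure(list(design = design, beta = beta,
                 counts_mirna = counts_mirna, counts_mrna = counts_mrna,
                 annotation = annotation, target_db = db,
                 truth = truth, config = cfg),
            class = "epichain_sim")
}

#' Write all simulated input files of a cohort to a directory
#' @param sim an `epichain_sim` (see [simulate_cohort()])
#' @param dir output directory (created if missing)
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_design(sim$design, file.path(dir, "design.csv"))
  write_matrix(sim$beta, file.path(dir, "beta.tsv"), "probe_id")
  write_matrix(sim$counts_mrna, file.path(dir, "counts_mrna.tsv"))
  write_matrix(sim$counts_mirna, file.path(dir, "counts_mirna.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_target_db(sim$target_db, file.path(dir, "targets.tsv"))
  invisible(dir)
}

#' Simulate Gaussian log2-expression for a paired two-race cohort
#'
#' A direct Gaussian analogue of the count generator: per-feature log2
#' expression with patient random effects, residual noise, and a planted
#' disease effect on a fraction of features (both races). Useful for
#' calibration studies of the testing machinery itself.
#'
#' @param n_features number of features
#' @param n_aa,n_ea patients per race
#' @param frac_de fraction of features with a planted effect
#' @param effect planted log2 effect size (sign random per feature)
#' @param patient_sd patient random-effect sd
#' @param residual_sd residual sd
#' @param seed RNG seed
#' @return list with `design`, `matrix` (features x samples log2 scale),
#'   `de_features` (planted ids), `signs`.
#' @export
simulate_expression_matrix <- function(n_features = 5000, n_aa = 8,
                                       n_ea = 8, frac_de = 0.10,
                                       effect = 1.5, patient_sd = 0.5,
                                       residual_sd = 1.0, seed = 1) {
  set.seed(seed)
  pid <- c(sprintf("aa%02d", seq_len(n_aa)), sprintf("ea%02d", seq_len(n_ea)))
  design <- study_design(data.frame(
    sample_id = c(paste0(pid, "_T"), paste0(pid, "_N")),
    patient_id = rep(pid, 2),
    race = rep(rep(RACES, c(n_aa, n_ea)), 2),
    tissue = rep(TISSUES, each = length(pid))))
  ids <- sprintf("g%05d", seq_len(n_features))
  n_de <- round(frac_de * n_features)
  signs <- integer(n_features)
  if (n_de > 0) signs[seq_len(n_de)] <- sample(c(-1L, 1L), n_de,
                                               replace = TRUE)
  base <- stats::rnorm(n_features, 6, 2)
  pat <- match(design$patient_id, unique(design$patient_id))
  tau <- matrix(stats::rnorm(n_features * length(pid)), nrow = n_features)
  shift <- outer(signs * effect, as.numeric(design$tissue == "tumor"))
  Y <- base + patient_sd * tau[, pat, drop = FALSE] + shift +
    residual_sd * matrix(stats::rnorm(n_features * nrow(design)),
                         nrow = n_features)
  dimnames(Y) <- list(ids, design$sample_id)
  list(design = design, matrix = Y, de_features = ids[signs != 0],
       signs = stats::setNames(signs, ids))
}

#' Score a set of calls against ground truth
#'
#' @param called character vector of called identifiers
#' @param truth character vector of true identifiers
#' @return list: `n_called`, `n_true`, `tp`, `fp`, `fdp` (false calls /
#'   max(1, total calls)), `sensitivity` (recovered / planted; `NaN` when
#'   nothing was planted).
#' @export
truth_eval <- function(called, truth) {
  called <- unique(called); truth <- unique(truth)
  unknown <- character(0)
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  list(n_called = length(called), n_true = length(truth),
       tp = tp, fp = fp,
       fdp = fp / max(1, length(called)),
       sensitivity = if (length(truth) == 0) NaN else tp / length(truth))
}
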