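#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Non-finite p-values (NA/NaN, e.g. from degenerate fits) are excluded
#' from the ranking and from the effective number of tests, and come back
#' as NaN.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA/NaN allowed)
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- is.finite(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    ec_value_error("p-values must lie in [0, 1]")
  q <- rep(NaN, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  names(q) <- names(p)
  q
}

#' Per-feature beta difference (tumor minus adjacent) within a stratum
#'
#' Delta-beta = mean beta over tumor samples minus mean beta over adjacent
#' non-tumor samples of the stratum ("ALL" pools both races).
#'
#' @param beta an `omics_matrix` of kind `beta`
#' @param design a `study_design`
#' @param stratum `"AA"`, `"EA"`, or `"ALL"`
#' @return named numeric vector, one value per feature.
#' @export
delta_beta <- function(beta, design, stratum = c("AA", "EA", "ALL")) {
  stratum <- match.arg(stratum)
  tum <- design_samples(design, stratum, "tumor")
  adj <- design_samples(design, stratum, "adjacent")
  if (length(tum) == 0)
    ec_value_error(paste0("stratum ", stratum, " is empty in the design"))
  rowMeans(beta[, tum, drop = FALSE]) - rowMeans(beta[, adj, drop = FALSE])
}

#' Per-feature fold change of group medians within a stratum
#'
#' FC = median over tumor samples / median over adjacent samples, with a
#' pseudo-count of 0.5 added to both medians only when either is zero.
#'
#' @param counts an `omics_matrix` of kind `counts` or `normalized`
#' @param design a `study_design`
#' @param stratum `"AA"`, `"EA"`, or `"ALL"`
#' @return named numeric vector of fold-change ratios.
#' @export
fold_change <- function(counts, design, stratum = c("AA", "EA", "ALL")) {
  stratum <- match.arg(stratum)
  tum <- design_samples(design, stratum, "tumor")
  adj <- design_samples(design, stratum, "adjacent")
  if (length(tum) == 0)
    ec_value_error(paste0("stratum ", stratum, " is empty in the design"))
  med <- function(cols) apply(unclass(counts)[, cols, drop = FALSE], 1,
                              stats::median)
  mt <- med(tum); ma <- med(adj)
  zero <- mt == 0 | ma == 0
  fc <- mt / ma
  fc[zero] <- (mt[zero] + 0.5) / (ma[zero] + 0.5)
  fc
}

#' Call significant features from contrast results and effect sizes
#'
#' Methylation: significant iff `q < q_max` and `|delta-beta| > dbeta_min`
#' (defaults 0.05 and 0.1). Expression (mrna/mirna): significant iff
#' `q < q_max`. The fold-change filter (`max(FC, 1/FC) > fc_min`, default
#' 2) is reported as a separate `passes_fc` flag for display subsets, not
#' as part of the core DE call.
#'
#' @param results contrast results for one (omic, contrast) family with `q`
#'   already filled (see [bh_adjust()])
#' @param effects named per-feature effect vector: delta-beta for
#'   methylation, fold-change ratio for expression
#' @param omic `"methylation"`, `"mrna"`, or `"mirna"`
#' @param q_max FDR threshold (strict `<`)
#' @param dbeta_min absolute beta-difference threshold (strict `>`)
#' @param fc_min fold-change threshold for the display flag
#' @return data.frame of differential calls: `feature_id`, `contrast`,
#'   `omic`, `q`, `effect`, `direction`, `significant`, `passes_fc`.
#' @export
call_significant <- function(results, effects,
                             omic = c("methylation", "mrna", "mirna"),
                             q_max = 0.05, dbeta_min = 0.1, fc_min = 2) {
  omic <- match.arg(omic)
  if (length(unique(results$contrast)) > 1)
    ec_consistency_error("results must come from a single contrast family")
  if (!setequal(results$feature_id, names(effects)))
    ec_consistency_error("feature sets of results and effects differ")
  eff <- unname(effects[match(results$feature_id, names(effects))])
  q <- results$q
  if (all(is.na(q)))
    ec_consistency_error("q is unset; apply bh_adjust per family first")
  if (omic == "methylation") {
    sig <- !is.na(q) & is.finite(q) & q < q_max & abs(eff) > dbeta_min
    direction <- ifelse(eff > 0, "up", ifelse(eff < 0, "down", NA))
    passes_fc <- rep(NA, length(q))
  } else {
    sig <- !is.na(q) & is.finite(q) & q < q_max
    direction <- ifelse(eff > 1, "up", ifelse(eff < 1, "down", NA))
    passes_fc <- pmax(eff, 1 / eff) > fc_min
  }
  data.frame(feature_id = results$feature_id,
             contrast = results$contrast,
             omic = omic, q = q, effect = eff, direction = direction,
             significant = sig, passes_fc = passes_fc)
}
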