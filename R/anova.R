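# Split-plot mixed ANOVA for the paired two-tissue, two-race design:
#   y_ijk = mu + tau_i + alpha_j + beta_k + gamma_jk + eps_ijk,
# patient tau_i ~ N(0, omega^2) random, eps ~ N(0, sigma^2), race j and
# tissue k fixed. With complete tumor/adjacent pairs the design is balanced
# within race and everything is available in closed form: cell means give
# the fixed effects, within-patient differences carry the tissue contrasts
# (the patient effect cancels), and the pooled variance of those
# differences estimates 2*sigma^2 on N - 2 degrees of freedom.

# internal: per-patient column indices, AA patients first
design_index <- function(design) {
  pat <- unique(as.data.frame(design)[, c("patient_id", "race")])
  pat <- pat[order(match(pat$race, RACES), pat$patient_id), ]
  key <- paste(design$patient_id, design$tissue)
  tum <- match(paste(pat$patient_id, "tumor"), key)
  adj <- match(paste(pat$patient_id, "adjacent"), key)
  list(patient_id = pat$patient_id, race = pat$race,
       tumor_sample = design$sample_id[tum],
       adjacent_sample = design$sample_id[adj],
       n_aa = sum(pat$race == "AA"), n_ea = sum(pat$race == "EA"))
}

# internal vectorized engine shared by fit_feature() and run_all().
# Y: features x samples matrix with colnames covering the design samples.
anova_engine <- function(Y, design) {
  idx <- design_index(design)
  if (idx$n_aa < 2 || idx$n_ea < 2)
    ec_dof_error("need at least 2 patients per race")
  miss <- setdiff(c(idx$tumor_sample, idx$adjacent_sample), colnames(Y))
  if (length(miss) > 0)
    ec_consistency_error(paste0("matrix is missing sample(s): ",
                                paste(miss, collapse = ", ")))
  Yt <- Y[, idx$tumor_sample, drop = FALSE]
  Ya <- Y[, idx$adjacent_sample, drop = FALSE]
  D <- Yt - Ya                      # within-patient tumor - adjacent
  S <- (Yt + Ya) / 2                # patient means
  aa <- idx$race == "AA"; ea <- !aa
  n_aa <- idx$n_aa; n_ea <- idx$n_ea; N <- n_aa + n_ea

  dbar_aa <- rowMeans(D[, aa, drop = FALSE])
  dbar_ea <- rowMeans(D[, ea, drop = FALSE])
  ss_d <- rowSums((D[, aa, drop = FALSE] - dbar_aa)^2) +
          rowSums((D[, ea, drop = FALSE] - dbar_ea)^2)
  sigma2 <- ss_d / (2 * (N - 2))
  sbar_aa <- rowMeans(S[, aa, drop = FALSE])
  sbar_ea <- rowMeans(S[, ea, drop = FALSE])
  ss_s <- rowSums((S[, aa, drop = FALSE] - sbar_aa)^2) +
          rowSums((S[, ea, drop = FALSE] - sbar_ea)^2)
  ms_patient <- 2 * ss_s / (N - 2)  # E = sigma^2 + 2*omega^2
  omega2 <- pmax(0, (ms_patient - sigma2) / 2)

  cell <- cbind(AA.tumor = rowMeans(Yt[, aa, drop = FALSE]),
                AA.adjacent = rowMeans(Ya[, aa, drop = FALSE]),
                EA.tumor = rowMeans(Yt[, ea, drop = FALSE]),
                EA.adjacent = rowMeans(Ya[, ea, drop = FALSE]))

  list(idx = idx, n_aa = n_aa, n_ea = n_ea, df = N - 2,
       est = cbind(AA = dbar_aa, EA = dbar_ea,
                   ALL = (dbar_aa + dbar_ea) / 2),
       sigma2 = sigma2, omega2 = omega2, cell = cell,
       degenerate = sigma2 == 0)
}

#' Fit the per-feature mixed ANOVA in closed form
#'
#' @param y named numeric vector of one feature's values, names being the
#'   design's sample ids
#' @param design a `study_design` with complete pairs and at least two
#'   patients per race
#' @return A `mixed_anova_fit` list: `grand_mean`, `race_effects`,
#'   `disease_effects`, `interaction` (2 x 2, sum-to-zero coding),
#'   `cell_means`, `sigma2`, `omega2`, `residual_df`, `n_per_race`,
#'   `degenerate`.
#' @export
fit_feature <- function(y, design) {
  if (is.null(names(y)))
    ec_consistency_error("y must be named by sample_id")
  Y <- matrix(y, nrow = 1, dimnames = list("feature", names(y)))
  eng <- anova_engine(Y, design)
  cm <- matrix(eng$cell[1, ], nrow = 2, byrow = TRUE,
               dimnames = list(RACES, TISSUES))
  mu <- mean(cm)
  alpha <- rowMeans(cm) - mu
  beta <- colMeans(cm) - mu
  gamma <- cm - mu - outer(alpha, rep(1, 2)) - outer(rep(1, 2), beta)
  structure(list(grand_mean = mu, race_effects = alpha,
                 disease_effects = beta, interaction = gamma,
                 cell_means = cm,
                 sigma2 = unname(eng$sigma2), omega2 = unname(eng$omega2),
                 residual_df = eng$df,
                 n_per_race = c(AA = eng$n_aa, EA = eng$n_ea),
                 degenerate = unname(eng$degenerate)),
            class = "mixed_anova_fit")
}

# tumor - adjacent contrast from an engine result, vectorized over features
contrast_from_engine <- function(eng, which) {
  est <- eng$est[, which]
  se2 <- switch(which,
    AA = 2 * eng$sigma2 / eng$n_aa,
    EA = 2 * eng$sigma2 / eng$n_ea,
    ALL = eng$sigma2 / 2 * (1 / eng$n_aa + 1 / eng$n_ea))
  se <- sqrt(se2)
  t <- ifelse(eng$degenerate, NaN, est / se)
  p <- ifelse(eng$degenerate, NaN, 2 * stats::pt(-abs(t), eng$df))
  data.frame(contrast = which, estimate = unname(est), se = unname(se),
             t = unname(t), df = eng$df, p = unname(p), q = NA_real_,
             reason = ifelse(eng$degenerate, "zero_variance", NA_character_))
}

#' Test one tumor-vs-adjacent contrast from a fitted mixed ANOVA
#'
#' `AA` and `EA` test the within-race tumor minus adjacent difference; `ALL`
#' tests the disease main effect, i.e. the equally weighted average of the
#' two race-specific differences. Standard errors use the pooled residual
#' variance with `N - 2` degrees of freedom; p-values are two-sided.
#' Degenerate (zero-variance) fits yield `p = NaN` with a reason code
#' rather than an error.
#'
#' @param fit a `mixed_anova_fit`
#' @param which `"AA"`, `"EA"`, or `"ALL"`
#' @return one-row data.frame: `contrast`, `estimate`, `se`, `t`, `df`,
#'   `p`, `q` (`NA`, filled later), `reason`.
#' @export
contrast_test <- function(fit, which = c("AA", "EA", "ALL")) {
  which <- match.arg(which)
  cm <- fit$cell_means
  est <- switch(which,
    AA = cm["AA", "tumor"] - cm["AA", "adjacent"],
    EA = cm["EA", "tumor"] - cm["EA", "adjacent"],
    ALL = ((cm["AA", "tumor"] - cm["AA", "adjacent"]) +
           (cm["EA", "tumor"] - cm["EA", "adjacent"])) / 2)
  n_aa <- fit$n_per_race["AA"]; n_ea <- fit$n_per_race["EA"]
  se2 <- switch(which,
    AA = 2 * fit$sigma2 / n_aa,
    EA = 2 * fit$sigma2 / n_ea,
    ALL = fit$sigma2 / 2 * (1 / n_aa + 1 / n_ea))
  se <- sqrt(unname(se2))
  if (fit$degenerate) {
    t <- NaN; p <- NaN; reason <- "zero_variance"
  } else {
    t <- unname(est) / se
    p <- 2 * stats::pt(-abs(t), fit$residual_df)
    reason <- NA_character_
  }
  data.frame(contrast = which, estimate = unname(est), se = se, t = t,
             df = fit$residual_df, p = p, q = NA_real_, reason = reason)
}

#' Fit and test all three contrasts for every feature of a matrix
#'
#' Count data must arrive on the modeling scale, i.e. `log2(normalized +
#' 0.5)`; beta-values must be converted to M-values first. The output is
#' deterministically ordered: features in input order, contrasts AA, EA,
#' ALL within each feature, and is identical however the features are
#' chunked.
#'
#' @param matrix numeric matrix or `omics_matrix` (kind `mvalue` or
#'   `normalized`), features x samples
#' @param design a `study_design`
#' @return data.frame with 3 rows per feature: `feature_id`, `contrast`,
#'   `estimate`, `se`, `t`, `df`, `p`, `q` (`NA`), `reason`.
#' @export
run_all <- function(matrix, design) {
  kind <- matrix_kind(matrix)
  if (!is.null(kind) && kind %in% c("beta", "counts"))
    ec_value_error(paste0("matrix of kind '", kind,
      "' must be transformed before modeling (beta -> M, counts -> ",
      "log2(normalized + 0.5))"))
  Y <- unclass(matrix)
  eng <- anova_engine(Y, design)
  per_contrast <- lapply(CONTRASTS, function(w) contrast_from_engine(eng, w))
  nfeat <- nrow(Y)
  out <- do.call(rbind, lapply(seq_along(CONTRASTS), function(ci) {
    data.frame(feature_id = rownames(Y), per_contrast[[ci]])
  }))
  # interleave to feature-major order: feature in input order, AA/EA/ALL
  out <- out[order(rep(seq_len(nfeat), times = 3),
                   rep(seq_along(CONTRASTS), each = nfeat)), ]
  rownames(out) <- NULL
  out
}
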