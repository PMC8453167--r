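#' Filter EPIC-style probes on QC flags and sex chromosomes
#'
#' Retains exactly the probes whose QC flag set is empty and whose
#' chromosome is neither chrX nor chrY, preserving the original row order.
#' This mirrors the usual array cleanup: dropping sex-chromosome probes,
#' non-CpG probes, probes within 10 bp of a common SNP or 15 bp of a
#' repetitive element, and multi-hit probes.
#'
#' @param matrix an `omics_matrix` of kind `beta`
#' @param annotation an `annotation_table` covering every matrix feature
#' @return list with `matrix` (kept probes), `tally` (named removals per
#'   flag; a probe with several flags counts under each), and
#'   `removed_total` (distinct probes removed).
#' @export
filter_probes <- function(matrix, annotation) {
  probes <- annotation$probes
  idx <- match(rownames(matrix), probes$probe_id)
  if (anyNA(idx))
    ec_annotation_error(paste0("probe(s) missing from annotation: ",
      paste(rownames(matrix)[is.na(idx)][seq_len(min(5, sum(is.na(idx))))],
            collapse = ", ")))
  ann <- probes[idx, ]
  flag_list <- strsplit(ann$qc_flags, ",", fixed = TRUE)
  sex_by_pos <- ann$chrom %in% c("chrX", "chrY")
  # a sex-chromosome location counts as a sex_chrom removal even if unflagged
  flag_list <- Map(function(fl, sx) unique(c(fl, if (sx) "sex_chrom")),
                   flag_list, sex_by_pos)
  tally <- vapply(QC_FLAGS,
                  function(f) sum(vapply(flag_list, function(x) f %in% x, TRUE)),
                  integer(1))
  removed <- vapply(flag_list, length, 1L) > 0
  list(matrix = matrix[!removed, , drop = FALSE],
       tally = tally,
       removed_total = sum(removed))
}

#' Convert beta-values to M-values
#'
#' M = log2(b / (1 - b)) with b clipped to \[epsilon, 1 - epsilon\] so the
#' transform stays finite at beta of exactly 0 or 1.
#'
#' @param beta number, vector, or `omics_matrix` of kind `beta`
#' @param epsilon clipping bound, in (0, 0.5); default `1e-6`
#' @return same shape as the input; an `omics_matrix` input comes back with
#'   kind `mvalue`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 0.5)
    ec_parameter_error("epsilon must lie strictly between 0 and 0.5")
  was_om <- inherits(beta, "omics_matrix")
  b <- pmin(pmax(unclass(beta), epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  if (was_om) {
    m <- matrix(m, nrow = nrow(beta), dimnames = dimnames(beta))
    m <- omics_matrix(m, "mvalue")
  } else if (is.matrix(beta)) {
    m <- matrix(m, nrow = nrow(beta), dimnames = dimnames(beta))
  }
  m
}

# TMM factor of one sample against the reference: trimmed, precision-
# weighted mean of per-feature log ratios (M), trimming jointly on M and on
# average abundance (A), restricted to features positive in both libraries.
tmm_one <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) return(NULL)
  o <- obs[pos]; r <- ref[pos]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- (log2(o / n_obs) + log2(r / n_ref)) / 2
  v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
          rank(a) >= lo_a & rank(a) <= hi_a
  f <- sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) normalization
#'
#' Computes per-library scaling factors by the TMM method: the reference is
#' the sample whose upper-quartile count fraction is closest to the mean
#' upper-quartile fraction; for every sample, log ratios (M) and average
#' log abundances (A) against the reference are computed over features with
#' positive counts in both libraries, doubly trimmed (`trim_m` on M,
#' `trim_a` on A), and combined as a precision-weighted mean; factors are
#' rescaled to geometric mean 1. The normalized matrix is counts per
#' million of the effective library size (library size x factor).
#'
#' @param counts an `omics_matrix` of kind `counts` (>= 2 samples, each
#'   with positive library size)
#' @param trim_m two-sided trim fraction on M (default 0.30)
#' @param trim_a two-sided trim fraction on A (default 0.05)
#' @return list with `factors` (data.frame `sample_id`, `library_size`,
#'   `factor`), `reference_sample`, and `normalized` (an `omics_matrix` of
#'   kind `normalized`).
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2)
    ec_parameter_error("TMM needs at least two samples")
  x <- unclass(counts)
  lib <- colSums(x)
  if (any(lib <= 0))
    ec_normalization_error(paste0("zero library size for sample(s): ",
      paste(colnames(x)[lib <= 0], collapse = ", ")))
  f75 <- apply(x, 2, function(col) stats::quantile(col, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(x)), function(i) {
    f <- tmm_one(x[, i], x[, ref], lib[i], lib[ref], trim_m, trim_a)
    if (is.null(f))
      ec_normalization_error(paste0("sample ", colnames(x)[i],
        " shares no positive feature with the reference"))
    f
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  norm <- t(t(x) / (lib * factors)) * 1e6
  list(factors = data.frame(sample_id = colnames(x),
                            library_size = unname(lib),
                            factor = unname(factors)),
       reference_sample = colnames(x)[ref],
       normalized = omics_matrix(norm, "normalized"))
}
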