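# Small in-code fixtures shared across test files.

make_design <- function(n_aa = 2, n_ea = 2) {
  pid <- c(sprintf("aa%02d", seq_len(n_aa)), sprintf("ea%02d", seq_len(n_ea)))
  study_design(data.frame(
    sample_id = c(paste0(pid, "_T"), paste0(pid, "_N")),
    patient_id = rep(pid, 2),
    race = rep(rep(c("AA", "EA"), c(n_aa, n_ea)), 2),
    tissue = rep(c("tumor", "adjacent"), each = length(pid))))
}

# feature values from per-patient (adjacent, tumor) pairs
make_paired_matrix <- function(design, adjacent, tumor, ids = NULL) {
  pid <- unique(design$patient_id)
  m <- matrix(NA_real_, nrow(adjacent), nrow(design),
              dimnames = list(ids %||% paste0("f", seq_len(nrow(adjacent))),
                              design$sample_id))
  m[, paste0(pid, "_N")] <- adjacent
  m[, paste0(pid, "_T")] <- tumor
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation with three probes used throughout the integration tests:
# cg1 in GENEA's promoter, cg2 in GENEA's body, cg3 in MIR589's promoter
make_toy_annotation <- function() {
  annotation_table(
    probes = data.frame(probe_id = c("cg1", "cg2", "cg3"),
                        chrom = "chr1", pos = c(100L, 200L, 300L),
                        qc_flags = ""),
    links = data.frame(
      probe_id = c("cg1", "cg2", "cg3"),
      gene_id = c("GENEA", "GENEA", "MIR589"),
      region = c("TSS200", "Body", "TSS1500"),
      gene_class = c("mrna", "mrna", "mirna")))
}

make_call_table <- function(feature_id, contrast, omic, q, effect,
                            significant = NULL) {
  direction <- if (omic == "methylation")
    ifelse(effect > 0, "up", "down") else ifelse(effect > 1, "up", "down")
  if (is.null(significant)) {
    significant <- if (omic == "methylation")
      q < 0.05 & abs(effect) > 0.1 else q < 0.05
  }
  data.frame(feature_id = feature_id, contrast = contrast, omic = omic,
             q = q, effect = effect, direction = direction,
             significant = significant,
             passes_fc = if (omic == "methylation") NA else
               pmax(effect, 1 / effect) > 2)
}
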