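# Shared vocabularies and error helpers.

RACES <- c("AA", "EA")
TISSUES <- c("tumor", "adjacent")
CONTRASTS <- c("AA", "EA", "ALL")
MATRIX_KINDS <- c("beta", "mvalue", "counts", "normalized")
REGIONS <- c("TSS1500", "TSS200", "UTR5", "FirstExon", "Body", "UTR3")
QC_FLAGS <- c("sex_chrom", "non_cpg", "snp_within_10bp",
              "repeat_within_15bp", "multi_hit")
# ordered from weakest to strongest evidence
EVIDENCE_LEVELS <- c("moderate", "high_confidence", "experimental")
GENE_CLASSES <- c("mrna", "mirna")

# Illumina promoter-proximal region labels used as the default promoter set.
PROMOTER_REGIONS_DEFAULT <- c("TSS1500", "TSS200", "UTR5", "FirstExon")

# Classed conditions so callers/tests can distinguish failure families.
ec_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "epichain_error")))
}

ec_format_error <- function(msg) ec_abort(msg, "epichain_format_error")
ec_value_error <- function(msg) ec_abort(msg, "epichain_value_error")
ec_parse_error <- function(msg) ec_abort(msg, "epichain_parse_error")
ec_design_error <- function(msg) ec_abort(msg, "epichain_design_error")
ec_parameter_error <- function(msg) ec_abort(msg, "epichain_parameter_error")
ec_annotation_error <- function(msg) ec_abort(msg, "epichain_annotation_error")
ec_consistency_error <- function(msg) ec_abort(msg, "epichain_consistency_error")
ec_normalization_error <- function(msg) ec_abort(msg, "epichain_normalization_error")
ec_dof_error <- function(msg) ec_abort(msg, "epichain_dof_error")
ec_io_error <- function(msg) ec_abort(msg, "epichain_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# inverse of the log2-logit (M-value) transform
inv_logit2 <- function(m) 1 / (1 + 2^(-m))
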