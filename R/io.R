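#' Construct and validate a study design
#'
#' A study design describes a paired two-tissue, two-race cohort: every
#' patient contributes exactly one tumor and one adjacent non-tumor sample,
#' and belongs to exactly one racial stratum (AA or EA).
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `race`
#'   (`"AA"`/`"EA"`), `tissue` (`"tumor"`/`"adjacent"`). Tokens are
#'   case-sensitive exact strings.
#' @return A validated `study_design` (a data.frame subclass).
#' @export
study_design <- function(df) {
  req <- c("sample_id", "patient_id", "race", "tissue")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    ec_format_error(paste0("design is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df)[, req]
  for (col in req) df[[col]] <- as.character(df[[col]])

  bad_race <- setdiff(unique(df$race), RACES)
  if (length(bad_race) > 0)
    ec_value_error(paste0("unknown race token(s): ",
                          paste(bad_race, collapse = ", ")))
  bad_tis <- setdiff(unique(df$tissue), TISSUES)
  if (length(bad_tis) > 0)
    ec_value_error(paste0("unknown tissue token(s): ",
                          paste(bad_tis, collapse = ", ")))
  if (anyDuplicated(df$sample_id))
    ec_format_error(paste0("duplicate sample_id(s): ",
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))

  for (p in unique(df$patient_id)) {
    rows <- df[df$patient_id == p, ]
    if (nrow(rows) != 2 || !setequal(rows$tissue, TISSUES))
      ec_design_error(paste0("patient ", p,
        " must have exactly one tumor and one adjacent sample"))
    if (length(unique(rows$race)) != 1)
      ec_design_error(paste0("patient ", p, " maps to more than one race"))
  }

  rownames(df) <- NULL
  class(df) <- c("study_design", "data.frame")
  df
}

#' Read a study design CSV
#'
#' @param path CSV with header `sample_id,patient_id,race,tissue`.
#' @return A validated `study_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) ec_io_error(paste0("no such file: ", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  study_design(df)
}

#' Write a study design CSV
#' @param design a `study_design`
#' @param path output CSV path
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Number of patients per race in a design
#' @param design a `study_design`
#' @return named integer vector `c(AA = , EA = )`
#' @export
design_counts <- function(design) {
  pat <- unique(design[, c("patient_id", "race")])
  c(AA = sum(pat$race == "AA"), EA = sum(pat$race == "EA"))
}

# sample ids for one (race, tissue) stratum; race "ALL" pools both
design_samples <- function(design, race = "ALL", tissue = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (race != "ALL") keep <- keep & design$race == race
  if (!is.null(tissue)) keep <- keep & design$tissue == tissue
  design$sample_id[keep]
}

#' Construct a feature-by-sample omics matrix with a declared value kind
#'
#' @param values numeric matrix (features in rows, samples in columns) with
#'   both dimnames set.
#' @param kind one of `"beta"`, `"mvalue"`, `"counts"`, `"normalized"`.
#'   `beta` values must lie in \[0, 1\]; `counts` must be non-negative
#'   integers.
#' @return An `omics_matrix` (numeric matrix with a `kind` attribute).
#' @export
omics_matrix <- function(values, kind) {
  if (!kind %in% MATRIX_KINDS)
    ec_value_error(paste0("unknown matrix kind: ", kind))
  values <- as.matrix(values)
  if (!is.numeric(values)) ec_parse_error("matrix values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    ec_format_error("omics matrix needs feature and sample names")
  if (anyDuplicated(rownames(values)))
    ec_format_error(paste0("duplicate feature id(s): ",
      paste(unique(rownames(values)[duplicated(rownames(values))]),
            collapse = ", ")))
  if (anyNA(values)) ec_value_error("matrix contains missing values")
  if (kind == "beta" && (min(values) < 0 || max(values) > 1))
    ec_value_error("beta values must lie in [0, 1]")
  if (kind == "counts" && (min(values) < 0 || any(values != round(values))))
    ec_value_error("counts must be non-negative integers")
  attr(values, "kind") <- kind
  class(values) <- c("omics_matrix", class(matrix()))
  values
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "kind") <- attr(x, "kind")
    class(out) <- class(x)
  }
  out
}

#' Value kind of an omics matrix
#' @param x an `omics_matrix` (or plain matrix, giving `NULL`)
#' @export
matrix_kind <- function(x) attr(x, "kind")

#' Read a feature-by-sample TSV matrix
#'
#' First column holds feature ids; remaining columns are samples.
#'
#' @param path TSV path
#' @param kind declared value kind (see [omics_matrix()])
#' @return An `omics_matrix`.
#' @export
read_matrix <- function(path, kind) {
  if (!file.exists(path)) ec_io_error(paste0("no such file: ", path))
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) ec_format_error("matrix TSV needs id column + samples")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    ec_parse_error(sprintf(
      "non-numeric cell at row %d (feature %s), column %s",
      bad[1], ids[bad[1]], colnames(vals)[bad[2]]))
  }
  rownames(num) <- ids
  omics_matrix(num, kind)
}

#' Write an omics matrix as TSV
#' @param mat matrix with dimnames
#' @param path output path
#' @param id_col name for the feature-id column
#' @export
write_matrix <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), fmt_num_df(as.data.frame(unclass(mat))),
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / validate a CpG annotation table
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based), `qc_flags` (comma-joined subset of the QC vocabulary, `""`
#'   for clean probes).
#' @param links data.frame with columns `probe_id`, `gene_id`, `region`,
#'   `gene_class` (zero rows allowed).
#' @return An `annotation_table` (list of the two validated frames).
#' @export
annotation_table <- function(probes, links) {
  preq <- c("probe_id", "chrom", "pos", "qc_flags")
  if (!all(preq %in% names(probes)))
    ec_format_error("annotation probes need probe_id, chrom, pos, qc_flags")
  probes <- as.data.frame(probes)[, preq]
  probes$probe_id <- as.character(probes$probe_id)
  probes$chrom <- as.character(probes$chrom)
  probes$pos <- as.integer(probes$pos)
  probes$qc_flags <- as.character(probes$qc_flags)
  if (anyDuplicated(probes$probe_id))
    ec_format_error(paste0("duplicate probe_id(s): ",
      paste(unique(probes$probe_id[duplicated(probes$probe_id)]),
            collapse = ", ")))
  if (anyNA(probes$pos) || any(probes$pos < 1))
    ec_value_error("probe positions must be integers >= 1 (1-based)")
  flag_tokens <- setdiff(
    unlist(strsplit(probes$qc_flags[probes$qc_flags != ""], ",")), QC_FLAGS)
  if (length(flag_tokens) > 0)
    ec_value_error(paste0("unknown qc flag(s): ",
                          paste(unique(flag_tokens), collapse = ", ")))

  lreq <- c("probe_id", "gene_id", "region", "gene_class")
  links <- as.data.frame(links)
  if (nrow(links) == 0)
    links <- data.frame(probe_id = character(), gene_id = character(),
                        region = character(), gene_class = character())
  if (!all(lreq %in% names(links)))
    ec_format_error("annotation links need probe_id, gene_id, region, gene_class")
  links <- links[, lreq]
  for (col in lreq) links[[col]] <- as.character(links[[col]])
  if (any(links$gene_id == "" | is.na(links$gene_id)))
    ec_value_error("every annotation link needs a non-empty gene_id")
  bad_reg <- setdiff(unique(links$region), REGIONS)
  if (length(bad_reg) > 0)
    ec_value_error(paste0("unknown region token(s): ",
                          paste(bad_reg, collapse = ", ")))
  bad_cls <- setdiff(unique(links$gene_class), GENE_CLASSES)
  if (length(bad_cls) > 0)
    ec_value_error(paste0("unknown gene class(es): ",
                          paste(bad_cls, collapse = ", ")))
  if (!all(links$probe_id %in% probes$probe_id))
    ec_consistency_error("annotation link refers to an unknown probe_id")

  rownames(probes) <- rownames(links) <- NULL
  structure(list(probes = probes, links = links),
            class = "annotation_table")
}

#' Read a CpG annotation TSV
#'
#' Columns: `probe_id`, `chrom`, `pos`, `qc_flags` (comma-joined, may be
#' empty), `links` (semicolon-joined `gene:region:class` triples, may be
#' empty).
#'
#' @param path TSV path
#' @return An `annotation_table`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) ec_io_error(paste0("no such file: ", path))
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  req <- c("probe_id", "chrom", "pos", "qc_flags", "links")
  if (!all(req %in% names(df)))
    ec_format_error("annotation TSV needs probe_id, chrom, pos, qc_flags, links")
  link_rows <- lapply(seq_len(nrow(df)), function(i) {
    s <- df$links[i]
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 3L
    if (any(bad))
      ec_parse_error(paste0("malformed link triple for probe ",
                            df$probe_id[i]))
    data.frame(probe_id = df$probe_id[i],
               gene_id = vapply(parts, `[`, "", 1),
               region = vapply(parts, `[`, "", 2),
               gene_class = vapply(parts, `[`, "", 3))
  })
  links <- do.call(rbind, link_rows)
  annotation_table(df[, c("probe_id", "chrom", "pos", "qc_flags")],
                   links %||% data.frame())
}

#' Write a CpG annotation TSV
#' @param annotation an `annotation_table`
#' @param path output path
#' @export
write_annotation <- function(annotation, path) {
  probes <- annotation$probes
  links <- annotation$links
  joined <- vapply(probes$probe_id, function(p) {
    l <- links[links$probe_id == p, , drop = FALSE]
    if (nrow(l) == 0) return("")
    paste(paste(l$gene_id, l$region, l$gene_class, sep = ":"),
          collapse = ";")
  }, "")
  out <- data.frame(probes, links = unname(joined), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / validate a miRNA target database
#'
#' @param df data.frame with columns `mirna_id`, `gene_id`, `evidence`
#'   (`experimental` > `high_confidence` > `moderate`).
#' @return A `target_db` data.frame.
#' @export
target_db <- function(df) {
  req <- c("mirna_id", "gene_id", "evidence")
  if (!all(req %in% names(df)))
    ec_format_error("target DB needs mirna_id, gene_id, evidence")
  df <- as.data.frame(df)[, req]
  for (col in req) df[[col]] <- as.character(df[[col]])
  bad_ev <- setdiff(unique(df$evidence), EVIDENCE_LEVELS)
  if (length(bad_ev) > 0)
    ec_value_error(paste0("unknown evidence level(s): ",
                          paste(bad_ev, collapse = ", ")))
  key <- paste(df$mirna_id, df$gene_id)
  if (anyDuplicated(key))
    ec_format_error(paste0("duplicate (mirna, gene) pair(s): ",
      paste(unique(key[duplicated(key)]), collapse = ", ")))
  rownames(df) <- NULL
  class(df) <- c("target_db", "data.frame")
  df
}

#' Read a miRNA target database TSV
#' @param path TSV with columns `mirna_id`, `gene_id`, `evidence`
#' @return A `target_db`.
#' @export
read_target_db <- function(path) {
  if (!file.exists(path)) ec_io_error(paste0("no such file: ", path))
  target_db(utils::read.delim(path, check.names = FALSE,
                              colClasses = "character"))
}

#' Write a miRNA target database TSV
#' @param db a `target_db`
#' @param path output path
#' @export
write_target_db <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# format numeric columns with 17 significant digits so write -> read
# round-trips doubles bit-exactly
fmt_num_df <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- df[[col]]
      s <- sprintf("%.17g", v)
      s[is.na(v) & !is.nan(v)] <- "NA"
      s[is.nan(v)] <- "NaN"
      df[[col]] <- s
    }
  }
  df
}

#' Write a pipeline result table as TSV
#'
#' Numeric columns are written with full (17 significant digit) precision so
#' that [read_results()] reproduces the table bit-exactly.
#'
#' @param result a data.frame result table
#' @param path output path
#' @export
write_results <- function(result, path) {
  ok <- tryCatch({
    utils::write.table(fmt_num_df(as.data.frame(result)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ec_io_error(paste0("cannot write results to ", path))
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path TSV path
#' @return data.frame with numeric columns restored
#' @export
read_results <- function(path) {
  if (!file.exists(path)) ec_io_error(paste0("no such file: ", path))
  df <- utils::read.delim(path, check.names = FALSE, na.strings = NULL,
                          colClasses = "character")
  for (col in names(df)) {
    v <- df[[col]]
    if (length(v) > 0 && all(v %in% c("TRUE", "FALSE", "NA"))) {
      df[[col]] <- as.logical(ifelse(v == "NA", NA, v))
      next
    }
    special <- v %in% c("NA", "NaN")
    conv <- suppressWarnings(as.numeric(v))
    # numeric iff every entry is NA/NaN or parses, with >=1 real number
    if (all(special | !is.na(conv)) && any(!special)) {
      conv[v == "NA"] <- NA_real_
      conv[v == "NaN"] <- NaN
      df[[col]] <- conv
    } else {
      df[[col]][v == "NA"] <- NA_character_
    }
  }
  df
}
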