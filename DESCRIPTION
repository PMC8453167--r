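Package: epichain
Title: Integrative Mixed-ANOVA Analysis of DNA Methylation, miRNA and mRNA
    Expression in Paired Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-feature two-way mixed ANOVA (race as a between-patient
    factor, tissue as a within-patient factor) for paired tumor / adjacent
    non-tumor multi-omics cohorts, with race-specific tumor-vs-adjacent
    contrasts, Benjamini-Hochberg FDR control, effect-size based calling of
    differentially methylated CpGs and differentially expressed mRNAs and
    miRNAs, and cross-layer integration: promoter mapping, reciprocally
    regulated DMDE genes, miRNA-target pairing, DNA-methylation to miRNA to
    mRNA regulatory chains, and detection of genes whose epigenetic driver
    switches between racial strata. Includes probe filtering, beta to
    M-value conversion, trimmed-mean-of-M-values (TMM) normalization, a
    fully linked synthetic cohort generator with ground truth, and a
    one-call pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    lme4,
    lmerTest
Config/testthat/edition: 3
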