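---
title: "Methods: mixed-ANOVA multi-omics integration in epichain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-ANOVA multi-omics integration in epichain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Hepatocellular carcinoma shows marked differences between African-American
(AA) and European-American (EA) patients, and part of that heterogeneity is
epigenetic: tumors may silence the same gene through promoter DNA
hypermethylation in one stratum and through miRNA over-expression in the
other. `epichain` implements a complete analysis path for paired
tumor / adjacent non-tumor cohorts profiled on three layers — CpG
methylation (array beta-values), miRNA counts, and mRNA counts — and the
cross-layer logic needed to expose such stratum-specific regulation.

## The model

For one feature, with patient $i$, race $j \in \{AA, EA\}$ and tissue
$k \in \{tumor, adjacent\}$:

$$ y_{ijk} = \mu + \tau_i + \alpha_j + \beta_k + \gamma_{jk} +
\varepsilon_{ijk}, \qquad \tau_i \sim N(0, \omega^2),\;
\varepsilon_{ijk} \sim N(0, \sigma^2), $$

a split-plot design: race is a between-patient factor, tissue a
within-patient factor, and the patient is a random block. Three contrasts
are tested per feature:

* **AA**: tumor minus adjacent within AA,
  $(\beta_1+\gamma_{11}) - (\beta_2+\gamma_{12})$;
* **EA**: the same within EA;
* **ALL**: the disease main effect, the *equally weighted* average of the
  two race-specific differences
  $(\beta_1-\beta_2)+\tfrac12(\gamma_{11}-\gamma_{12})+\tfrac12(\gamma_{21}-\gamma_{22})$,
  regardless of the stratum sample sizes.

Because every patient contributes both tissues, the design is balanced
within race and the fit is closed-form. Writing $d_{ij}$ for the
within-patient tumor-minus-adjacent difference (which cancels $\tau_i$),
the contrast estimates are stratum means of $d_{ij}$, and

$$ \hat\sigma^2 = \frac{\sum_j \sum_i (d_{ij} - \bar d_j)^2}{2\,(N-2)},
\qquad \text{df} = N - 2, $$

with $N$ the total number of patients. Standard errors are
$\sqrt{2\hat\sigma^2/n_j}$ within a race and
$\sqrt{\tfrac{\hat\sigma^2}{2}(1/n_{AA} + 1/n_{EA})}$ for ALL; p-values are
two-sided t. Design choices made here, deliberately and testably:

* a single pooled residual variance with $N-2$ df rather than per-race
  paired t-tests — this is what the one joint model implies;
* $\hat\omega^2$ by method of moments from the between-patient mean
  square, truncated at zero; the contrasts never depend on it because the
  patient effect cancels in $d_{ij}$;
* zero-variance features are flagged (`p = NaN`, reason code) instead of
  erroring, so batch runs never abort;
* the closed form is validated in the test suite against a numeric REML
  oracle (`lmerTest`, Satterthwaite df). The comparison is restricted to
  interior fits: on the $\omega^2 = 0$ boundary REML pools the two
  variance strata and the split-plot residual df no longer applies, so the
  two estimators legitimately differ there.

Counts are modeled on `log2(TMM-normalized + 0.5)`; beta-values on the
M-value scale `log2(b/(1-b))` with clipping at `epsilon = 1e-6`
(keeps M finite at beta of exactly 0 or 1 with negligible distortion).
Both scale choices are package decisions: variance stabilization for a
Gaussian linear model, and the standard logit scale for methylation.

## Preprocessing

* **Probe filtering** removes probes with any QC flag (non-CpG, SNP within
  10 bp, repeat within 15 bp, multi-hit) or a sex-chromosome location,
  reporting a per-flag tally in which a multiply-flagged probe counts under
  each flag but only once in the removed total.
* **TMM normalization** is implemented in-package: reference column by
  upper-quartile fraction closest to the mean; per-sample log-ratios (M)
  and abundances (A) over features positive in both libraries; double trim
  (30% on M, 5% on A, the community defaults — the trims are tunable);
  precision-weighted mean of the retained M; factors rescaled to geometric
  mean 1; normalized output in counts per million of the effective library
  size. The implementation is cross-checked against `edgeR` in the test
  suite to 1e-10.

## Calling rules

Benjamini–Hochberg adjustment is applied separately within each
(omic, contrast) family, mirroring how per-stratum counts are reported.
DMCs require `q < 0.05` **and** `|delta-beta| > 0.1` (strict
inequalities); DE mRNAs/miRNAs require `q < 0.05` only. Fold changes are
ratios of group *medians* of normalized counts, with a 0.5 pseudo-count
only when a median is zero; `max(FC, 1/FC) > 2` is kept as a separate
display flag, not a gate on the DE call. Delta-beta and FC are computed
per stratum, consistently with each other.

## Integration

* **Promoter map**: genes to probes through annotation links whose region
  is in {TSS1500, TSS200, UTR5, FirstExon} by default — the
  promoter-proximal labels of the EPIC manifest vocabulary; configurable
  because "promoter" has no single canonical definition.
* **DM genes**: at least one significant promoter DMC; each supporting
  probe is kept as provenance.
* **DMDE records**: one per (gene, probe) with the gene DE in the same
  contrast; a probe is *reciprocal* when methylation direction opposes
  expression direction, and a gene is reciprocal when any supporting probe
  is — probes are never averaged, so multi-probe promoters with
  conflicting signs stay visible.
* **Target pairs**: DE miRNA x DE mRNA pairs present in the user-supplied
  target database at `experimental` or `high_confidence` evidence by
  default; opposite directions mark reciprocal pairs, same-direction pairs
  are retained flagged.
* **Chains**: probe -> miRNA -> mRNA triples built from reciprocal DMDE
  miRNAs and reciprocal target pairs; directions alternate by
  construction (hypo -> up -> down or hyper -> down -> up).
* **Mechanism-switch genes**: DE in both races, driven by an AA-exclusive
  DE miRNA (reciprocal target relation) while promoter-methylated
  reciprocally in EA only, with the gene not DM in AA at all. A
  same-direction requirement between the races is available as an option
  but off by default, since either direction pattern is mechanistically
  interpretable.
* **Correlation**: Pearson r between each DMDE probe's M-values and
  `log2(normalized expression + 0.5)` over the stratum's samples; the
  headline summary is the fraction of records with `|r| > 0.5`. The
  absolute value is a deliberate reading of a sign-ambiguous convention:
  reciprocal regulation implies negative r, so `|r|` is the conservative
  superset.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the pipeline targets:
8 AA + 8 EA patients, each with one tumor and one adjacent sample.
Methylation is generated on the log2-logit scale as baseline + patient
effect (sd 0.5) + planted disease shift + noise (sd 0.8), then
inverse-logit to (0,1). Planted shifts are *calibrated*: the generator
numerically inverts the noise-smoothed expectation of the inverse logit so
that a planted site's expected delta-beta equals the requested effect
(default 0.25) at that site's baseline — a plain logit shift would
systematically undershoot because noise shrinks expected beta toward 0.5.
Counts are negative binomial (dispersion 0.1) with log-normal library
sizes (sd 0.3, exercising TMM nontrivially), gene abundances log-normal,
and planted log2 fold changes (default 1.5). Default planted fractions
are race-asymmetric (EA-dominant methylation, AA-dominant miRNA effects),
the structure this pipeline exists to resolve.

Structural truth is planted explicitly: reciprocal DMDE genes per stratum,
full chains (promoter probe -> shared DE miRNA -> reciprocal DE targets),
and switch genes (DE-shared gene, AA-only DE miRNA driver in the target
DB, EA-only reciprocal promoter DMC). Background annotation links use
non-promoter regions only, so the planted promoter structure alone
defines DM/DMDE/switch ground truth, and the target DB carries 5x decoy
pairs between non-DE features so integration specificity is testable.
What the generator does **not** emulate: the bimodal beta distribution of
real arrays (baselines are uniform on (0.05, 0.95)), batch effects,
probe cross-hybridization structure, and realistic genomic coordinates.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under the stated model, not performance on real
EPIC data.

`simulate_expression_matrix()` is the Gaussian analogue (log2 scale,
patient sd 0.5, residual sd 1.0) used for calibration studies of the
testing machinery itself, where count noise is not the question.

## Calibration results computed by this package

`scripts/acceptance.R` recomputes, from fresh simulations at the defaults
above (5,000 features, 20 seeded replicates, 10% planted effects), the
mean false-discovery proportion of DMC calls and of DE-gene calls at the
`q < 0.05` thresholds; the test suite asserts both stay within the
nominal 5% (plus two Monte-Carlo standard errors). The suite also checks
type-I error of the ALL contrast on null data, parameter recovery
(planted effect 1.0, sigma 1, 8+8 patients, 200 features, |bias| < 0.1),
and exact recovery of planted switch genes with zero decoys on an
asymmetric cohort with strong planted effects (delta-beta 0.3, log2 FC 3
— chosen a priori so that planted structure is unambiguous at n = 8+8
and any false or missed call signals a logic error rather than noise).

## Problem sizes and numerical notes

Simulated checks run at desk scale — hundreds to a few thousand features
per cohort, 5,000 for the calibration targets — chosen as the package's
own test-design sizes; all operations are vectorized across features, and
a full-array run (850k probes) is a few minutes of the same code paths.
Ties in TMM trimming follow average ranks; the TMM reference sample's
factor is 1 by construction before rescaling; BH leaves NaN p-values out
of both ranking and the effective test count; all pipeline outputs are
written with 17 significant digits so TSV round-trips are bit-exact; the
pipeline itself draws no random numbers, so reruns are bit-identical.

## Known limitations

* Only complete paired designs are supported; unbalanced or missing-pair
  cohorts would need general REML and are out of scope.
* Variances are per-feature; no empirical-Bayes moderation is applied.
* The switch-gene rule is set-logic on calls, so its sensitivity inherits
  the per-layer calling thresholds; borderline features flip whole
  records.
* Pathway/enrichment analysis is out of scope; exported gene lists are
  suitable input for any enrichment tool.
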