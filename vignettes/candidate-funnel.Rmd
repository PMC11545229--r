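---
title: "The PDX candidate funnel: model, thresholds and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PDX candidate funnel: model, thresholds and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxfunnel)
```

## The analysis model

`pdxfunnel` identifies tumor-progression candidate proteins from a cohort
design in which each patient contributes four tissues to one 4-plex iTRAQ
run: adjacent noncancerous epithelium (N), primary tumor (T), and first-
and second-generation patient-derived xenograft tumors (P1, P2). Reporter
channels 114–117 are assigned to N/T/P1/P2 by default
(`channel_assignment()`); any bijection onto the 4-plex set is accepted.

The pipeline's statistical core is deliberately simple and mirrors common
practice in discovery proteomics:

* **Relative quantification.** For every peptide-spectrum match (PSM)
  with a positive reference intensity, each tumor channel yields one
  spectrum-level ratio `log2(channel / N)`. Zero or negative intensities
  are treated as missing before the ratio is formed — no pseudocounts —
  so absence propagates as absence, never as `NaN` or `-Inf`.
* **Protein ratios.** The protein-level log2 ratio per (patient,
  comparison) is the **median** of its spectrum ratios. The acquisition
  software used in such studies aggregates without documenting the
  statistic; the median is robust to single aberrant spectra and is
  configurable to the mean (`quant_config(aggregation = "mean")`).
  Proteins need at least two quantifiable spectra; by default the minimum
  is evaluated per (protein, patient) over any comparison, because the
  quantifiability rule is stated per protein, not per ratio. A stricter
  per-cell variant is available (`count_scope = "per_comparison"`).
* **Normalization.** Each (patient, comparison) column is centered by
  subtracting its median log2 ratio. Median centering leaves the
  post-normalization *mean* of a skewed column nonzero — which is why
  per-column mean statistics in this design are typically slightly
  negative: the down-regulated tail of a tumor/normal comparison is
  heavier than the up-regulated one.
* **Dysregulation calls.** With per-column mean *m* and standard
  deviation *s* (sample SD, divisor n−1; configurable to n), a protein is
  `over` when its ratio **strictly** exceeds *m* + *s* and `under` when
  strictly below *m* − *s*; a ratio exactly at a threshold is
  `unchanged`. Under a normal null this calls Φ(−1) ≈ 15.87% of proteins
  on each side; the test suite verifies this calibration on a
  10,000-protein null-only cohort to within ±1.1 percentage points.
  Statistics are computed after normalization, matching the order
  (transform, normalize, then threshold) of the procedure the pipeline
  implements.
* **Conservation and consensus.** A protein is conserved within a
  patient when it carries the same call in all three comparisons; it
  must be quantified in all three to be eligible, because "simultaneously
  dysregulated in T, P1 and P2" presupposes all three measured. A protein
  is a cohort candidate when conserved in the same direction in ≥ k of n
  patients (default 3 of 5). Up and down tallies are independent; the
  pathological case of a protein reaching k in both directions is kept
  and flagged `conflict` rather than silently dropped.
* **Transcript concordance.** An up candidate is confirmed when its
  gene's RNA fold change strictly exceeds 2 in T, P1 and P2 of at least
  3 patient groups; down candidates need fold changes strictly below 0.5.
  The source wording alternates between "more than three" and "at least
  three" patient groups for the two directions; with RNA typically
  available for only four of five groups we read both as the same ≥ 3
  rule and expose `concordance_min_patients` for the stricter reading.
  Genes without RNA data are non-concordant and flagged `no_rna_data`
  rather than dropped.

Two details are genuine open choices rather than settled conventions, and
both are configurable:

* *PSM counting.* The identification rule "at least two peptide-spectrum
  matches per protein" can be read as total PSMs or as unique peptides.
  Default is total PSMs per (patient, protein) — each iTRAQ run is one
  patient, so identification is per run —
  with `identification_config(count_unique_peptides = TRUE)` for the
  unique-peptide reading.
* *Keratin rule.* "Keratins excluded" is implemented as a gene-symbol
  pattern, `^KRT(AP)?[0-9]` (KRT1…KRT86 plus the KRTAP family), which is
  the reproducible reading of a contaminant exclusion; the pattern is a
  parameter.

## Fidelity metrics

PDX fidelity — whether xenograft proteomes preserve the primary tumor's
profile — is summarized at the level where it is measurable:

* `pairwise_profile_correlation()` computes Pearson r between ratio
  columns on their shared proteins (≥ 3 required; smaller overlaps are
  reported as skipped). The default pair set is all within-patient
  comparison pairs.
* `quantification_coverage()` histograms proteins by the number of
  patient groups in which they were quantified.
* `pca_profiles()` and `hierarchical_cluster()` operate on proteins
  quantified in at least 4 patient groups (the "quantified in at least
  four analyses" selection; we read "analyses" as patient groups, not
  individual columns) and then complete cases. Clustering uses
  1 − Pearson r distance with average linkage — the tool used in such
  studies does not document its metric, so we fix a standard,
  reproducible one. PCA loadings follow a fixed sign convention (the
  largest-magnitude element of each loading vector is positive) so
  scores are reproducible across platforms.

## What the synthetic cohort emulates

`simulate_cohort()` generates PSM tables, transcript tables and ground
truth with the statistical structure the analysis assumes. Its defaults
are the study conditions the pipeline is designed for:

* **Cohort shape.** 5 patients, 6,000-protein union, 3 comparisons per
  patient.
* **Null ratio structure.** Per-column null log2 ratios are Normal(μ0,
  σ0) with μ0 ~ U(−0.26, −0.05) and σ0 ~ U(0.77, 1.17) — the observed
  range of per-comparison means and SDs in this design (slightly
  negative means, SDs around 1).
* **Detection and depth.** Each protein carries a lognormal latent
  spectral depth (meanlog 1.125, sdlog 0.95); per (protein, patient) PSM
  counts are Poisson around it and detection means ≥ 1 PSM. The
  lognormal heterogeneity is what produces the characteristic U-shaped
  coverage profile (many proteins in all groups, many in exactly one);
  its two parameters were calibrated once so that ≈ 46% of the
  quantified union is present in all five groups and a quantified
  protein averages ~6 spectra. A homogeneous Bernoulli detection model
  cannot produce this profile jointly with the ≥ 2-spectra rule, which
  is why depth heterogeneity, not a flat detection probability, is the
  generative mechanism.
* **Patient effect.** Null proteins receive a protein-specific shift
  (SD 0.6 log2 units) shared by the three comparisons of one patient.
  This single term reproduces the two structural observations the
  fidelity stage checks: within-patient column correlations around
  0.3–0.6 and clustering of profiles by patient.
* **Spiked proteins.** 60 up- and 200 down-regulated proteins carry a
  shift of u·σ0 with u ~ U(1.2, 2.5), attenuated ×0.9 per PDX
  generation (T full, P1 90%, P2 81%). The conservation noise — how much
  the realized shift varies — is drawn **per patient** (SD 0.15 in σ0
  units) and shared across that patient's three generations: a patient's
  tumor expresses the driver at its own level, and the xenografts
  inherit it. Spiked proteins do not additionally receive the null
  patient effect; they model drivers whose dysregulation is conserved
  by construction, which is exactly the hypothesis class the funnel is
  built to recover. Spike expression probability is 1 by default and is
  a dial for studying cohort heterogeneity.
* **Nuisance structure.** Additive log2 spectrum noise (SD 0.3),
  lognormal reference intensities, 20 keratin decoys generated like
  nulls, and ~5% of PSMs violating the length or confidence filters, so
  the identification stage has real work to do.
* **Transcripts.** RNA fold changes cover the first 4 of 5 patients
  (RNA-seq rarely covers the full proteome cohort). Spiked genes are
  concordant with probability 0.8 (fold changes 2^±N(1.8, 0.35)); null
  genes with probability 0.05; all others draw fold changes 2^N(0, 0.5).

The generator does **not** simulate raw spectra, retention times,
isotope-impurity crosstalk between reporter channels, ratio compression
from co-isolation, peptide-level missingness mechanisms beyond Poisson
sampling, or shared-peptide protein-inference ambiguity. Passing the
recovery and calibration tests therefore shows that the pipeline's logic
is correct under its own model assumptions — not that those assumptions
capture every artifact of real iTRAQ data.

## Evaluation conventions

`truth_evaluation()` reports sensitivity against the *evaluable* spiked
proteins: those expressed and quantified in at least k patient groups.
A spiked protein quantified in only two groups cannot reach a 3-of-5
consensus under any method, so counting it against the pipeline would
measure the detection model, not the funnel logic; the
all-spiked-denominator figure is reported alongside
(`sensitivity_all`). The false-discovery proportion is the fraction of
candidates whose truth status is null or keratin. An empty candidate set
reports sensitivity 0 and FDP 0 with a `degenerate` flag.

## Numerical and degenerate-input conventions

* Strict inequalities at every threshold (call thresholds, fold-change
  bounds, screen gates), following the "exceeding"/"below" wording of
  the rules they implement.
* Ties in the median are resolved by the standard midpoint convention.
* All-missing normalization columns, sub-2-protein statistics columns,
  rank-deficient PCA requests, single-column clustering, a missing
  anchor gene, and k > n consensus requests raise errors that name the
  offending column or parameter; empty PSM tables and empty candidate
  sets flow through as empty results.
* Output row order is always a pure function of content (direction,
  then accession; patient, then comparison), so re-serialization is
  byte-identical.
* Correlation p-values use the t-transform of Pearson r; SD uses the
  n−1 divisor unless configured otherwise.

## Problem sizes in the test suite

The property suite exercises the pipeline at the cohort scale it is
meant for: the shared fixture is the default 5-patient, 6,000-protein
cohort (~145k PSMs, a few seconds to generate and analyze), the null
calibration uses a 10,000-protein null-only cohort, and oracle checks
(Pearson, PCA eigen-shares, average-linkage merge order, median/mean
aggregation) run on ≤ 5×5 toys against brute-force implementations
written from first principles. Unbiasedness of median aggregation is
checked at 1,000 proteins × 51 spectra.

## Known limitations

* Protein inference is by accession identity only; shared peptides and
  protein groups are out of scope.
* No isotope-impurity correction or ratio-compression modeling; ratios
  are taken as extracted.
* No moderated-variance or p-value-based differential testing — the
  mean ± 1 SD rule is the implemented method, with its known property
  of calling a fixed ~32% of a null column dysregulated before any
  conservation filtering. The funnel's specificity comes from the
  conservation and consensus stages, not from the per-column caller.
* The co-expression screen computes correlations on a user-supplied
  expression matrix; it does not fetch public cohort data.
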