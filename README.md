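# pdxfunnel

Candidate-funnel analysis for 4-plex iTRAQ proteomes of matched
noncancerous, primary-tumor and patient-derived xenograft (PDX) tissues.

## The problem

Tumor tissues that successfully engraft as PDX models are enriched for
progression-competent clones, and proteins that stay dysregulated through
serial PDX generations are strong candidates for progression drivers. A
common design profiles, for each patient, four tissues in one iTRAQ run —
adjacent noncancerous epithelium (N, reporter 114), primary tumor (T, 115),
first-generation PDX tumor (P1, 116) and second-generation PDX tumor
(P2, 117) — and asks which proteins are consistently dysregulated in
T/N, P1/N and P2/N across a cohort, and whether the transcriptome agrees.

`pdxfunnel` implements that analysis as a tidyverse-native pipeline:

1. **Identification filtering** — PSMs kept when peptide length > 7 aa and
   confidence *p* < 0.01; keratin contaminants excluded; proteins need at
   least 2 PSMs per patient run.
2. **Quantification** — per PSM, log2(reporter/reference) ratios; per
   protein, the median spectrum ratio; proteins need at least 2
   quantifiable spectra; each (patient, comparison) column is
   median-centered.
3. **Dysregulation calls** — per column with mean *m* and standard
   deviation *s* of all protein log2 ratios, a protein is *over* when its
   ratio exceeds *m* + *s* and *under* when it falls below *m* − *s*
   (strict inequalities).
4. **Within-patient conservation** — over (under) in all of T/N, P1/N and
   P2/N: the triple intersection of the per-tissue Venn diagram.
5. **Cross-patient consensus** — same-direction conservation in ≥ k of n
   patient groups (default 3 of 5).
6. **Transcript concordance** — RNA fold change > 2 (up) or < 0.5 (down)
   in T, P1 and P2 of ≥ 3 patient groups.

Around the funnel, the package provides PDX-fidelity metrics (pairwise
Pearson correlation of profiles, union-coverage histograms, PCA and
average-linkage clustering of the (patient, comparison) columns), an
anchor-gene co-expression screen (`coexpression_screen()`), and a seeded
synthetic-cohort generator with ground truth (`simulate_cohort()`) so the
whole pipeline is testable without any external data.

## Worked example

```r
library(pdxfunnel)

cohort <- simulate_cohort(simulation_config(seed = 1))
result <- run_pipeline(cohort$psms, cohort$transcripts)
result
#> Candidate funnel: 145121 PSMs -> 132409 retained -> 5531 proteins quantified
#>   cross-patient consensus: 43 up, 127 down
#>   transcript-concordant:   34 up, 102 down

truth_evaluation(result$candidates, cohort$truth, result$quant, k = 3)
#> Recovery: 169/199 evaluable spiked proteins (sensitivity 0.849); FDP 0.006 (1/170 candidates)
```

Of ~145k simulated PSMs, 5,531 proteins survive identification and
quantifiability filtering; 170 reach the 3-of-5 cross-patient consensus
(43 up, 127 down) and 136 of those are confirmed by transcript fold
changes. Against the simulator's ground truth, 84.9% of the recoverable
spiked proteins are found, with one false candidate. Column statistics,
calls, conserved sets and the stage-count table are all in the result
(`result$stats`, `result$calls`, `result$within_patient`,
`tidy(result)`); `autoplot(result)`, `plot_coverage()` and
`autoplot(pca_profiles(...))` draw the standard diagnostics, and
`render_report()` serializes the funnel.

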