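Package: pdxfunnel
Title: Candidate Funnel Analysis for iTRAQ Proteomes of Patient-Derived Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidyverse-native pipeline for identifying tumor-progression
    candidate proteins from matched noncancerous, primary-tumor, and
    patient-derived xenograft (PDX) tissues quantified with 4-plex iTRAQ.
    Implements peptide-spectrum-match confidence filtering, reporter-ion
    ratio aggregation to protein-level log2 ratios, median normalization,
    mean plus/minus one standard deviation dysregulation calls,
    within-patient conservation across tumor generations, cross-patient
    consensus, and transcript fold-change concordance, together with
    PDX-fidelity metrics (pairwise profile correlation, quantification
    coverage, PCA, hierarchical clustering) and a seeded synthetic-cohort
    generator with ground truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
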