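# In-code fixtures shared across test files. The default cohort and its
# pipeline run are generated once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(simulation_config(seed = 1))
  }
  .fixture_env$cohort
}

default_run <- function() {
  if (is.null(.fixture_env$run)) {
    co <- default_cohort()
    .fixture_env$run <- run_pipeline(co$psms, co$transcripts)
  }
  .fixture_env$run
}

# one PSM row with overridable fields
make_psm <- function(patient_id = "06", protein_accession = "P1",
                     gene_symbol = "GENE1", peptide_sequence = "ACDEFGHIK",
                     confidence_p = 0.001, intensity_N = 100,
                     intensity_T = 100, intensity_P1 = 100,
                     intensity_P2 = 100,
                     peptide_length = nchar(peptide_sequence)) {
  tibble::tibble(patient_id, protein_accession, gene_symbol,
                 peptide_sequence, peptide_length, confidence_p,
                 intensity_N, intensity_T, intensity_P1, intensity_P2)
}

# long quant tibble from named ratio vectors; values[[i]] is the ratio
# vector of protein i across the given columns
make_quant <- function(ratios, patient_id = "06", comparison = "T/N",
                       accessions = paste0("P", seq_along(ratios))) {
  tibble::tibble(
    protein_accession = accessions,
    gene_symbol = paste0("G", seq_along(ratios)),
    patient_id = patient_id,
    comparison = comparison,
    log2_ratio = ratios,
    spectrum_count = 5L,
    n_spectra = 5L)
}

# calls tibble builder: labels is a named list patient -> c(T = , P1 =, P2 =)
make_calls <- function(protein_accession, patient_id, labels) {
  tibble::tibble(
    protein_accession = protein_accession,
    gene_symbol = paste0("G_", protein_accession),
    patient_id = patient_id,
    comparison = rep(c("T/N", "P1/N", "P2/N"),
                     length.out = length(protein_accession)),
    log2_ratio = 0,
    label = labels)
}
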