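#' Within-patient conservation of dysregulation across tumor generations
#'
#' A protein is conserved up (down) within a patient when it is called
#' `over` (`under`) in all three comparisons T/N, P1/N and P2/N of that
#' patient. Only proteins quantified in all three comparisons are eligible;
#' direction conflicts (e.g. over in T but under in P1) are conserved in
#' neither direction. This is the triple intersection of the per-tissue
#' Venn diagram.
#'
#' @param calls A calls tibble from [classify_proteins()] (any number of
#'   patients).
#' @return A tibble `patient_id`, `protein_accession`, `gene_symbol`,
#'   `direction` (`"up"`/`"down"`), one row per conserved protein per
#'   patient.
#' @export
within_patient_consensus <- function(calls) {
  eligible <- calls |>
    filter(.data$label != "not_quantified",
           .data$comparison %in% COMPARISONS)
  sets <- eligible |>
    group_by(.data$patient_id, .data$protein_accession, .data$gene_symbol) |>
    summarize(n_comp = n_distinct(.data$comparison),
              n_over = sum(.data$label == "over"),
              n_under = sum(.data$label == "under"),
              .groups = "drop") |>
    filter(.data$n_comp == length(COMPARISONS)) |>
    mutate(direction = case_when(
      .data$n_over == length(COMPARISONS) ~ "up",
      .data$n_under == length(COMPARISONS) ~ "down",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$direction))
  sets |>
    select("patient_id", "protein_accession", "gene_symbol", "direction") |>
    arrange(.data$patient_id, .data$direction, .data$protein_accession)
}

#' Cross-patient consensus of conserved dysregulation
#'
#' A protein enters the consensus candidate set with direction d when it is
#' conserved in direction d within at least `k` of the `n` patient groups.
#' Up and down tallies are kept separately; a protein reaching `k` in both
#' directions is emitted in both rows with `conflict = TRUE` rather than
#' silently dropped.
#'
#' @param per_patient Output of [within_patient_consensus()].
#' @param k Minimum number of supporting patient groups (default 3).
#' @param n_patients Total number of patient groups; defaults to the number
#'   of distinct patients observed.
#' @return A candidate tibble: `protein_accession`, `gene_symbol`,
#'   `direction`, `n_supporting_patients`, `supporting_patients`
#'   (comma-separated sorted patient ids), `conflict`.
#' @export
cross_patient_consensus <- function(per_patient, k = 3, n_patients = NULL) {
  n <- n_patients %||% n_distinct(per_patient$patient_id)
  if (k < 1 || (n > 0 && k > n)) {
    abort(paste0("consensus threshold k = ", k,
                 " must lie in 1..n_patients (n = ", n, ")"))
  }
  if (nrow(per_patient) == 0) {
    return(tibble(protein_accession = character(), gene_symbol = character(),
                  direction = character(),
                  n_supporting_patients = integer(),
                  supporting_patients = character(), conflict = logical()))
  }
  tallies <- per_patient |>
    group_by(.data$protein_accession, .data$gene_symbol, .data$direction) |>
    summarize(
      n_supporting_patients = n_distinct(.data$patient_id),
      supporting_patients = paste(sort(unique(.data$patient_id)),
                                  collapse = ","),
      .groups = "drop")
  hits <- filter(tallies, .data$n_supporting_patients >= k)
  hits |>
    group_by(.data$protein_accession) |>
    mutate(conflict = n() > 1) |>
    ungroup() |>
    arrange(.data$direction, .data$protein_accession)
}

#' Transcript fold-change concordance of candidate proteins
#'
#' An up candidate is transcript-concordant when its gene's RNA fold change
#' strictly exceeds `up_fold` in all three tumor tissues (T, P1, P2) of at
#' least `min_patients` patient groups; a down candidate needs fold changes
#' strictly below `down_fold` likewise. A patient with a missing tissue
#' value does not support concordance. Genes absent from the transcript
#' table are non-concordant with `rna_status = "no_rna_data"`.
#'
#' @param candidates A candidate tibble from [cross_patient_consensus()].
#' @param transcripts A long transcript tibble (see
#'   [read_transcript_table()]).
#' @param up_fold,down_fold Strict linear fold-change bounds
#'   (defaults 2.0 and 0.5).
#' @param min_patients Minimum supporting patient groups (default 3).
#' @param tissues Tissues that must all pass (default T, P1, P2).
#' @return `candidates` with added columns `n_concordant_patients`,
#'   `transcript_concordant`, `rna_status`.
#' @export
transcript_concordance <- function(candidates, transcripts,
                                   up_fold = 2, down_fold = 0.5,
                                   min_patients = 3,
                                   tissues = c("T", "P1", "P2")) {
  stopifnot(down_fold < 1, up_fold > 1)
  if (nrow(candidates) == 0) {
    return(mutate(candidates, n_concordant_patients = integer(),
                  transcript_concordant = logical(),
                  rna_status = character()))
  }
  support <- candidates |>
    select("protein_accession", "gene_symbol", "direction") |>
    inner_join(filter(transcripts, .data$tissue %in% tissues),
               by = "gene_symbol", relationship = "many-to-many") |>
    mutate(passes = coalesce(if_else(.data$direction == "up",
                                     .data$fold_change > up_fold,
                                     .data$fold_change < down_fold),
                             FALSE)) |>
    group_by(.data$protein_accession, .data$direction, .data$patient_id) |>
    summarize(patient_supports = sum(.data$passes) == length(tissues) &&
                n() == length(tissues),
              .groups = "drop") |>
    group_by(.data$protein_accession, .data$direction) |>
    summarize(n_concordant_patients = sum(.data$patient_supports),
              .groups = "drop")

  out <- candidates |>
    left_join(support, by = c("protein_accession", "direction")) |>
    mutate(
      rna_status = if_else(is.na(.data$n_concordant_patients),
                           "no_rna_data", "ok"),
      n_concordant_patients = coalesce(.data$n_concordant_patients, 0L),
      transcript_concordant = .data$n_concordant_patients >= min_patients)
  arrange(out, .data$direction, .data$protein_accession)
}
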