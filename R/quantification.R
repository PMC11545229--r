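#' Quantification settings
#'
#' @param min_quantifiable_spectra Minimum number of quantifiable spectra
#'   for a protein to be considered quantifiable (default 2).
#' @param aggregation Statistic summarizing spectrum-level log2 ratios to
#'   the protein level: `"median"` (default) or `"mean"`.
#' @param count_scope Whether the spectrum minimum is evaluated per
#'   (protein, patient) over any comparison (`"per_patient"`, default,
#'   reading the rule as stated per protein) or separately per comparison
#'   cell (`"per_comparison"`).
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(min_quantifiable_spectra = 2,
                         aggregation = c("median", "mean"),
                         count_scope = c("per_patient", "per_comparison")) {
  stopifnot(min_quantifiable_spectra >= 1)
  structure(
    list(min_quantifiable_spectra = as.integer(min_quantifiable_spectra),
         aggregation = match.arg(aggregation),
         count_scope = match.arg(count_scope)),
    class = "quant_config")
}

#' Compute spectrum-level log2 ratios against the reference channel
#'
#' For every PSM and every non-reference tissue (T, P1, P2) where both the
#' tissue intensity and the reference (N) intensity are present and
#' strictly positive, emits one ratio `log2(tissue / N)`. Zero, negative or
#' missing intensities yield absence, never `NaN`.
#'
#' @param psms A filtered PSM tibble with tissue-labelled intensity columns.
#' @return A tibble with columns `spectrum_id` (input row index),
#'   `protein_accession`, `gene_symbol`, `patient_id`, `comparison`,
#'   `log2_ratio`.
#' @export
compute_spectrum_ratios <- function(psms) {
  ref <- psms$intensity_N
  ref_ok <- !is.na(ref) & ref > 0
  pieces <- lapply(COMPARISONS, function(comp) {
    tis <- comparison_tissue(comp)
    num <- psms[[paste0("intensity_", tis)]]
    ok <- ref_ok & !is.na(num) & num > 0
    tibble(
      spectrum_id = which(ok),
      protein_accession = psms$protein_accession[ok],
      gene_symbol = psms$gene_symbol[ok],
      patient_id = psms$patient_id[ok],
      comparison = comp,
      log2_ratio = log2(num[ok] / ref[ok])
    )
  })
  bind_rows(pieces) |>
    arrange(.data$spectrum_id, match(.data$comparison, COMPARISONS))
}

#' Aggregate spectrum ratios to protein-level log2 ratios
#'
#' Per (protein, patient, comparison) the spectrum-level log2 ratios are
#' summarized with the configured statistic (median by default). Proteins
#' with fewer quantifiable spectra than the configured minimum are not
#' quantifiable: their cells are absent from the output. The spectrum count
#' per (protein, patient) is recorded.
#'
#' @param ratios Output of [compute_spectrum_ratios()].
#' @param config A [quant_config()].
#' @return A long protein quantification tibble (`protein_accession`,
#'   `gene_symbol`, `patient_id`, `comparison`, `log2_ratio`,
#'   `spectrum_count`, `n_spectra`), one row per quantified cell.
#' @export
aggregate_protein_ratios <- function(ratios, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  agg_fun <- switch(config$aggregation, median = median, mean = mean)

  patient_counts <- ratios |>
    group_by(.data$protein_accession, .data$patient_id) |>
    summarize(spectrum_count = n_distinct(.data$spectrum_id),
              .groups = "drop")

  cells <- ratios |>
    group_by(.data$protein_accession, .data$gene_symbol, .data$patient_id,
             .data$comparison) |>
    summarize(log2_ratio = agg_fun(.data$log2_ratio),
              n_spectra = n_distinct(.data$spectrum_id),
              .groups = "drop") |>
    left_join(patient_counts, by = c("protein_accession", "patient_id"))

  keep <- if (config$count_scope == "per_patient") {
    cells$spectrum_count >= config$min_quantifiable_spectra
  } else {
    cells$n_spectra >= config$min_quantifiable_spectra
  }
  cells[keep, ] |>
    select("protein_accession", "gene_symbol", "patient_id", "comparison",
           "log2_ratio", "spectrum_count", "n_spectra") |>
    arrange(.data$protein_accession, .data$patient_id,
            match(.data$comparison, COMPARISONS))
}

#' Median-center each (patient, comparison) column
#'
#' Subtracts the column median of the non-missing log2 ratios from every
#' ratio of that (patient, comparison), so each column's post-normalization
#' median is zero. Missing cells remain missing. The operation is
#' idempotent.
#'
#' @param quant A long protein quantification tibble.
#' @return The tibble with normalized `log2_ratio`.
#' @export
median_normalize <- function(quant) {
  empty <- quant |>
    group_by(.data$patient_id, .data$comparison) |>
    summarize(n_ok = sum(!is.na(.data$log2_ratio)), .groups = "drop") |>
    filter(.data$n_ok == 0)
  if (nrow(empty) > 0) {
    abort(paste0("cannot normalize all-missing column(s): ",
                 paste(column_key(empty$patient_id, empty$comparison),
                       collapse = ", ")))
  }
  quant |>
    group_by(.data$patient_id, .data$comparison) |>
    mutate(log2_ratio = .data$log2_ratio -
             median(.data$log2_ratio, na.rm = TRUE)) |>
    ungroup()
}
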