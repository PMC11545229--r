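#' Per-comparison ratio statistics
#'
#' Mean and standard deviation of the (normalized) protein log2 ratios of
#' each (patient, comparison) column, together with the mean +/- 1 SD
#' thresholds used for dysregulation calling.
#'
#' @param quant A long protein quantification tibble (normally after
#'   [median_normalize()]).
#' @param sd_divisor `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @return A tibble with columns `patient_id`, `comparison`, `n_quantified`,
#'   `mean`, `sd`, `lower_threshold`, `upper_threshold`.
#' @export
comparison_stats <- function(quant, sd_divisor = c("n-1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  stats <- quant |>
    group_by(.data$patient_id, .data$comparison) |>
    summarize(n_quantified = sum(!is.na(.data$log2_ratio)),
              mean = mean(.data$log2_ratio, na.rm = TRUE),
              sd = sd(.data$log2_ratio, na.rm = TRUE),
              .groups = "drop")
  if (sd_divisor == "n") {
    stats$sd <- stats$sd * sqrt((stats$n_quantified - 1) / stats$n_quantified)
  }
  low <- stats$n_quantified < 2
  if (any(low)) {
    abort(paste0("need >= 2 quantified ratios to compute statistics for ",
                 "column(s): ",
                 paste(column_key(stats$patient_id[low],
                                  stats$comparison[low]), collapse = ", ")))
  }
  stats |>
    mutate(lower_threshold = .data$mean - .data$sd,
           upper_threshold = .data$mean + .data$sd) |>
    arrange(.data$patient_id, match(.data$comparison, COMPARISONS))
}

#' Classify proteins as over-, under-expressed or unchanged
#'
#' A protein is called `over` in a column when its log2 ratio strictly
#' exceeds that column's mean + 1 SD, `under` when it falls strictly below
#' mean - 1 SD, `unchanged` otherwise (a ratio exactly at a threshold is
#' unchanged), and `not_quantified` when the ratio is missing.
#'
#' @param quant A long protein quantification tibble.
#' @param stats Output of [comparison_stats()] computed on the same matrix.
#' @return A calls tibble: `protein_accession`, `gene_symbol`, `patient_id`,
#'   `comparison`, `log2_ratio`, `label`.
#' @export
classify_proteins <- function(quant, stats) {
  quant_cols <- distinct(quant, .data$patient_id, .data$comparison)
  stat_cols <- distinct(stats, .data$patient_id, .data$comparison)
  miss <- anti_join(quant_cols, stat_cols, by = c("patient_id", "comparison"))
  extra <- anti_join(stat_cols, quant_cols, by = c("patient_id", "comparison"))
  if (nrow(miss) > 0 || nrow(extra) > 0) {
    bad <- bind_rows(miss, extra)
    abort(paste0("stats/matrix column mismatch for: ",
                 paste(column_key(bad$patient_id, bad$comparison),
                       collapse = ", ")))
  }
  quant |>
    left_join(select(stats, "patient_id", "comparison",
                     "lower_threshold", "upper_threshold"),
              by = c("patient_id", "comparison")) |>
    mutate(label = case_when(
      is.na(.data$log2_ratio) ~ "not_quantified",
      .data$log2_ratio > .data$upper_threshold ~ "over",
      .data$log2_ratio < .data$lower_threshold ~ "under",
      TRUE ~ "unchanged")) |>
    select("protein_accession", "gene_symbol", "patient_id", "comparison",
           "log2_ratio", "label")
}

#' Count dysregulation calls per column
#'
#' Convenience summary mirroring the per-comparison over/under counting of
#' an iTRAQ screen.
#'
#' @param calls Output of [classify_proteins()].
#' @return A tibble `patient_id`, `comparison`, `n_over`, `n_under`,
#'   `n_unchanged`, `n_quantified`.
#' @export
count_calls <- function(calls) {
  calls |>
    group_by(.data$patient_id, .data$comparison) |>
    summarize(n_over = sum(.data$label == "over"),
              n_under = sum(.data$label == "under"),
              n_unchanged = sum(.data$label == "unchanged"),
              n_quantified = sum(.data$label != "not_quantified"),
              .groups = "drop") |>
    arrange(.data$patient_id, match(.data$comparison, COMPARISONS))
}
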