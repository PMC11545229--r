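#' Pipeline settings
#'
#' Bundles the per-stage configurations of the candidate funnel. Unknown
#' arguments are rejected so that a typo cannot silently fall back to a
#' default.
#'
#' @param identification An [identification_config()].
#' @param quantification A [quant_config()].
#' @param sd_divisor SD divisor for [comparison_stats()] (`"n-1"` or
#'   `"n"`).
#' @param consensus_k Minimum supporting patient groups for the
#'   cross-patient consensus (default 3).
#' @param concordance_up_fold,concordance_down_fold Strict linear RNA
#'   fold-change bounds (defaults 2 and 0.5).
#' @param concordance_min_patients Minimum patient groups for transcript
#'   concordance (default 3).
#' @param fidelity_min_patients Minimum patient groups per protein for
#'   PCA/clustering (default 4).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(identification = identification_config(),
                            quantification = quant_config(),
                            sd_divisor = "n-1",
                            consensus_k = 3,
                            concordance_up_fold = 2,
                            concordance_down_fold = 0.5,
                            concordance_min_patients = 3,
                            fidelity_min_patients = 4) {
  stopifnot(inherits(identification, "identification_config"),
            inherits(quantification, "quant_config"),
            sd_divisor %in% c("n-1", "n"),
            consensus_k >= 1)
  structure(
    list(identification = identification,
         quantification = quantification,
         sd_divisor = sd_divisor,
         consensus_k = as.integer(consensus_k),
         concordance_up_fold = concordance_up_fold,
         concordance_down_fold = concordance_down_fold,
         concordance_min_patients = as.integer(concordance_min_patients),
         fidelity_min_patients = as.integer(fidelity_min_patients)),
    class = "pipeline_config")
}

#' Run the full candidate funnel
#'
#' Orchestrates the staged analysis: PSM confidence filtering, spectrum
#' ratio computation, protein-level aggregation with the quantifiability
#' rule, median normalization, mean +/- 1 SD dysregulation calling,
#' within-patient conservation across T/P1/P2, cross-patient consensus,
#' and (when transcript data are given) RNA fold-change concordance.
#' Identical inputs and configuration yield identical outputs.
#'
#' @param psms A PSM tibble ([read_psm_table()] or
#'   `simulate_cohort()$psms`).
#' @param transcripts Optional long transcript tibble.
#' @param config A [pipeline_config()].
#' @return A list of class `funnel_result` holding every stage output:
#'   `filter` (the [filter_psms()] result), `quant` (normalized matrix),
#'   `stats`, `calls`, `call_counts`, `within_patient`, `candidates`
#'   (concordance-flagged when transcripts were supplied), `funnel`
#'   (per-stage count table) and `config`.
#' @export
run_pipeline <- function(psms, transcripts = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  flt <- filter_psms(psms, config$identification)
  ratios <- compute_spectrum_ratios(flt$psms)
  quant <- aggregate_protein_ratios(ratios, config$quantification) |>
    median_normalize()
  stats <- comparison_stats(quant, sd_divisor = config$sd_divisor)
  calls <- classify_proteins(quant, stats)
  call_counts <- count_calls(calls)
  within <- within_patient_consensus(calls)
  n_pat <- n_distinct(quant$patient_id)
  candidates <- cross_patient_consensus(within, k = config$consensus_k,
                                        n_patients = n_pat)
  if (!is.null(transcripts)) {
    candidates <- transcript_concordance(
      candidates, transcripts,
      up_fold = config$concordance_up_fold,
      down_fold = config$concordance_down_fold,
      min_patients = config$concordance_min_patients)
  }

  within_counts <- within |>
    count(.data$patient_id, .data$direction, name = "count")
  funnel <- bind_rows(
    tibble(stage = "psms_input", detail = "all", direction = NA_character_,
           count = flt$n_input),
    tibble(stage = "psms_retained", detail = "all",
           direction = NA_character_, count = flt$n_retained),
    tibble(stage = "proteins_quantified", detail = "all",
           direction = NA_character_,
           count = n_distinct(quant$protein_accession)),
    call_counts |>
      pivot_longer(c("n_over", "n_under"), names_to = "direction",
                   values_to = "count") |>
      mutate(stage = "dysregulated",
             detail = column_key(.data$patient_id, .data$comparison),
             direction = if_else(.data$direction == "n_over", "up",
                                 "down")) |>
      select("stage", "detail", "direction", "count"),
    within_counts |>
      mutate(stage = "within_patient_conserved",
             detail = .data$patient_id) |>
      select("stage", "detail", "direction", "count"),
    candidates |>
      count(.data$direction, name = "count") |>
      mutate(stage = "cross_patient_consensus", detail = "all") |>
      select("stage", "detail", "direction", "count"),
    if (!is.null(transcripts)) {
      candidates |>
        filter(.data$transcript_concordant) |>
        count(.data$direction, name = "count") |>
        mutate(stage = "transcript_concordant", detail = "all") |>
        select("stage", "detail", "direction", "count")
    }
  ) |>
    mutate(count = as.integer(.data$count))

  out <- list(filter = flt, quant = quant, stats = stats, calls = calls,
              call_counts = call_counts, within_patient = within,
              candidates = candidates, funnel = funnel, config = config)
  attr(out$candidates, "cohort_seed") <- attr(psms, "cohort_seed")
  structure(out, class = "funnel_result")
}

#' Per-patient Venn region counts of dysregulated proteins
#'
#' For each patient and direction, counts proteins in each region of the
#' three-set Venn diagram of the T/N, P1/N and P2/N dysregulated sets
#' (the triple intersection is the within-patient conserved set).
#'
#' @param calls A calls tibble from [classify_proteins()].
#' @return A tibble `patient_id`, `direction`, `region` (e.g. `"T"`,
#'   `"T&P1"`, `"T&P1&P2"`), `count`, with exclusive region counts.
#' @export
venn_summary <- function(calls) {
  target <- c(up = "over", down = "under")
  regions <- lapply(names(target), function(dir) {
    lab <- target[[dir]]
    calls |>
      filter(.data$label == lab) |>
      mutate(tissue = comparison_tissue(.data$comparison)) |>
      group_by(.data$patient_id, .data$protein_accession) |>
      summarize(region = paste(
        intersect(c("T", "P1", "P2"), .data$tissue), collapse = "&"),
        .groups = "drop") |>
      count(.data$patient_id, .data$region, name = "count") |>
      mutate(direction = dir)
  })
  all_regions <- c("T", "P1", "P2", "T&P1", "T&P2", "P1&P2", "T&P1&P2")
  grid <- tidyr::expand_grid(
    patient_id = sort(unique(calls$patient_id)),
    direction = names(target), region = all_regions)
  grid |>
    left_join(bind_rows(regions),
              by = c("patient_id", "direction", "region")) |>
    mutate(count = coalesce(.data$count, 0L))
}

#' Serialize a funnel report
#'
#' `format = "tsv"` writes the stage-count table (round-trippable with
#' [read_funnel_report()]); `format = "text"` writes a human-readable
#' summary including the per-patient conserved (common-up / common-down)
#' counts ordered by patient id.
#'
#' @param result A `funnel_result` from [run_pipeline()].
#' @param path Output path.
#' @param format `"tsv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(result, path, format = c("tsv", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "funnel_result"))
  funnel <- result$funnel
  if (format == "tsv") {
    readr::write_tsv(funnel, path, na = "", progress = FALSE)
    return(invisible(path))
  }
  lines <- c("Candidate funnel report", "=======================")
  totals <- filter(funnel, .data$detail == "all")
  for (i in seq_len(nrow(totals))) {
    lines <- c(lines, sprintf(
      "%-28s%s%d", totals$stage[i],
      if (is.na(totals$direction[i])) "      "
      else sprintf(" %-5s", totals$direction[i]),
      totals$count[i]))
  }
  lines <- c(lines, "", "Within-patient conserved proteins (T & P1 & P2):")
  wp <- filter(funnel, .data$stage == "within_patient_conserved") |>
    pivot_wider(names_from = "direction", values_from = "count",
                values_fill = 0L) |>
    arrange(.data$detail)
  if (!"up" %in% names(wp)) wp$up <- 0L
  if (!"down" %in% names(wp)) wp$down <- 0L
  for (i in seq_len(nrow(wp))) {
    lines <- c(lines, sprintf("  patient %-6s up %4d   down %4d",
                              wp$detail[i], wp$up[i], wp$down[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a TSV funnel report
#'
#' @param path Path written by [render_report()] with `format = "tsv"`.
#' @return The stage-count tibble.
#' @export
read_funnel_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    stage = readr::col_character(),
    detail = readr::col_character(),
    direction = readr::col_character(),
    count = readr::col_integer()), na = "", progress = FALSE)
}

#' @export
print.funnel_result <- function(x, ...) {
  g <- glance(x)
  cat("Candidate funnel:", g$n_psms, "PSMs ->", g$n_psms_retained,
      "retained ->", g$n_proteins_quantified, "proteins quantified\n")
  cat("  cross-patient consensus:", g$n_consensus_up, "up,",
      g$n_consensus_down, "down\n")
  if (!is.na(g$n_concordant_up)) {
    cat("  transcript-concordant:  ", g$n_concordant_up, "up,",
        g$n_concordant_down, "down\n")
  }
  invisible(x)
}

#' @describeIn run_pipeline One row per funnel stage (the stage-count
#'   table).
#' @param x A `funnel_result`.
#' @param ... Unused.
#' @export
tidy.funnel_result <- function(x, ...) x$funnel

#' @describeIn run_pipeline One-row summary of the funnel counts.
#' @export
glance.funnel_result <- function(x, ...) {
  funnel <- x$funnel
  pick <- function(stage, dir = NULL) {
    rows <- funnel[funnel$stage == stage & funnel$detail == "all", ]
    if (!is.null(dir)) rows <- rows[!is.na(rows$direction) &
                                      rows$direction == dir, ]
    if (nrow(rows) == 0) NA_integer_ else sum(rows$count)
  }
  has_rna <- any(funnel$stage == "transcript_concordant")
  zero_if <- function(v) if (is.na(v) && has_rna) 0L else v
  tibble(
    n_psms = pick("psms_input"),
    n_psms_retained = pick("psms_retained"),
    n_proteins_quantified = pick("proteins_quantified"),
    n_consensus_up = coalesce(pick("cross_patient_consensus", "up"), 0L),
    n_consensus_down = coalesce(pick("cross_patient_consensus", "down"),
                                0L),
    n_concordant_up = zero_if(pick("transcript_concordant", "up")),
    n_concordant_down = zero_if(pick("transcript_concordant", "down")))
}
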