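#' Identification filter settings
#'
#' Confidence criteria applied to PSM tables before quantification: peptide
#' length strictly greater than `min_peptide_length` amino acids, peptide
#' confidence p-value strictly below `max_confidence_p`, optional exclusion
#' of keratins, and at least `min_psms_per_protein` surviving PSMs per
#' protein within each patient's run.
#'
#' @param min_peptide_length Retained peptides must be longer than this
#'   (strict; default 7 aa).
#' @param max_confidence_p Retained PSMs must have confidence p strictly
#'   below this (default 0.01).
#' @param min_psms_per_protein Minimum surviving PSMs per (patient, protein)
#'   (default 2).
#' @param exclude_keratins Drop keratin PSMs (default `TRUE`).
#' @param keratin_pattern Regular expression on gene symbols defining a
#'   keratin; the default matches KRT followed by digits plus the KRTAP
#'   family.
#' @param count_unique_peptides If `TRUE`, the per-protein minimum counts
#'   distinct peptide sequences instead of total PSMs.
#' @return A list of class `identification_config`.
#' @export
identification_config <- function(min_peptide_length = 7,
                                  max_confidence_p = 0.01,
                                  min_psms_per_protein = 2,
                                  exclude_keratins = TRUE,
                                  keratin_pattern = "^KRT(AP)?[0-9]",
                                  count_unique_peptides = FALSE) {
  stopifnot(min_peptide_length > 0, max_confidence_p > 0,
            min_psms_per_protein > 0)
  structure(
    list(min_peptide_length = min_peptide_length,
         max_confidence_p = max_confidence_p,
         min_psms_per_protein = as.integer(min_psms_per_protein),
         exclude_keratins = isTRUE(exclude_keratins),
         keratin_pattern = keratin_pattern,
         count_unique_peptides = isTRUE(count_unique_peptides)),
    class = "identification_config")
}

#' Flag keratin PSMs by gene symbol
#'
#' Keratins are abundant skin/hair contaminants of tissue proteomics and are
#' excluded from candidate lists. Records without a gene symbol are never
#' flagged.
#'
#' @param psms A PSM tibble.
#' @param keratin_pattern Regular expression on gene symbols.
#' @return `psms` with a logical `is_keratin` column.
#' @export
flag_keratins <- function(psms, keratin_pattern = "^KRT(AP)?[0-9]") {
  psms$is_keratin <- !is.na(psms$gene_symbol) &
    grepl(keratin_pattern, psms$gene_symbol)
  psms
}

#' Filter PSMs on identification confidence
#'
#' Applies the rules in a fixed order (peptide length, confidence p,
#' keratin, per-protein PSM count); each removed PSM is attributed to the
#' first rule it fails, so the report is deterministic and removals plus
#' retentions add up to the input count. The per-protein minimum is
#' evaluated within each patient's run. A PSM missing the field a rule needs
#' fails that rule.
#'
#' @param psms A PSM tibble (see [read_psm_table()]).
#' @param config An [identification_config()].
#' @return A list of class `psm_filter_result` with elements
#'   `psms` (retained records), `report` (tibble of per-rule removal
#'   counts plus input/retained totals), and `excluded_proteins`
#'   (accessions fully removed, with the responsible rule).
#' @export
filter_psms <- function(psms, config = identification_config()) {
  stopifnot(inherits(config, "identification_config"))
  n_input <- nrow(psms)
  reason <- rep(NA_character_, n_input)

  fail_len <- is.na(psms$peptide_length) |
    !(psms$peptide_length > config$min_peptide_length)
  reason[is.na(reason) & fail_len] <- "peptide_length"

  fail_p <- is.na(psms$confidence_p) |
    !(psms$confidence_p < config$max_confidence_p)
  reason[is.na(reason) & fail_p] <- "confidence_p"

  if (config$exclude_keratins) {
    is_ker <- !is.na(psms$gene_symbol) &
      grepl(config$keratin_pattern, psms$gene_symbol)
    reason[is.na(reason) & is_ker] <- "keratin"
  }

  surviving <- is.na(reason)
  key <- paste(psms$patient_id, psms$protein_accession, sep = "\r")
  if (config$count_unique_peptides) {
    counts <- tapply(psms$peptide_sequence[surviving], key[surviving],
                     function(x) length(unique(x)))
  } else {
    counts <- table(key[surviving])
  }
  low <- names(counts)[counts < config$min_psms_per_protein]
  reason[surviving & key %in% low] <- "min_psms_per_protein"

  retained <- psms[is.na(reason), , drop = FALSE]
  rules <- c("peptide_length", "confidence_p", "keratin",
             "min_psms_per_protein")
  report <- tibble(
    rule = rules,
    n_removed = vapply(rules, function(r) sum(reason == r, na.rm = TRUE),
                       integer(1), USE.NAMES = FALSE)
  )

  removed <- psms[!is.na(reason), c("patient_id", "protein_accession"),
                  drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  kept_keys <- unique(key[is.na(reason)])
  removed_keys <- paste(removed$patient_id, removed$protein_accession,
                        sep = "\r")
  excluded <- removed[!removed_keys %in% kept_keys, , drop = FALSE] |>
    distinct(.data$patient_id, .data$protein_accession, .data$reason) |>
    arrange(.data$patient_id, .data$protein_accession)

  structure(
    list(psms = retained,
         report = report,
         n_input = n_input,
         n_retained = nrow(retained),
         excluded_proteins = as_tibble(excluded)),
    class = "psm_filter_result")
}

#' @export
print.psm_filter_result <- function(x, ...) {
  cat("PSM identification filter:", x$n_input, "input,", x$n_retained,
      "retained\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  removed by %-22s %d\n", paste0(x$report$rule[i], ":"),
                x$report$n_removed[i]))
  }
  invisible(x)
}
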