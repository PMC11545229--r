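# Tabular IO. Canonical dialect: tab-separated, UTF-8, '.' decimal, empty
# string = missing. All writers order rows as a pure function of content so
# re-serialization is byte-identical.

psm_meta_cols <- c("patient_id", "protein_accession", "gene_symbol",
                   "peptide_sequence", "peptide_length", "confidence_p")

#' Read a PSM-level quantification table
#'
#' One row per peptide-spectrum match (PSM). The file must contain the
#' metadata columns `patient_id`, `protein_accession`, `gene_symbol`,
#' `peptide_sequence`, `peptide_length`, `confidence_p`, and one reporter
#' intensity column per 4-plex channel, named `intensity_114` ..
#' `intensity_117`. The channel assignment maps those to tissue-labelled
#' columns `intensity_N`, `intensity_T`, `intensity_P1`, `intensity_P2`.
#' Empty cells are preserved as missing (`NA`), never coerced to zero.
#' Extra columns are tolerated and dropped.
#'
#' @param path Path to a TSV file.
#' @param assignment A [channel_assignment()].
#' @return A tibble of PSM records with tissue-labelled intensity columns.
#' @export
read_psm_table <- function(path, assignment = channel_assignment()) {
  stopifnot(inherits(assignment, "channel_assignment"))
  channel_cols <- paste0("intensity_", unname(assignment))
  required <- c(psm_meta_cols, channel_cols)

  header <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE))
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    abort(paste0("schema error in '", path, "': missing required column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }

  spec <- readr::cols(
    patient_id = readr::col_character(),
    protein_accession = readr::col_character(),
    gene_symbol = readr::col_character(),
    peptide_sequence = readr::col_character(),
    peptide_length = readr::col_integer(),
    confidence_p = readr::col_double(),
    .default = readr::col_guess()
  )
  for (cc in channel_cols) spec$cols[[cc]] <- readr::col_double()
  # readr's own parse warning is redundant: problems() is turned into an
  # error with row numbers below
  tbl <- suppressWarnings(
    readr::read_tsv(path, col_types = spec, na = "", progress = FALSE))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0(
      "parse error in '", path, "' at row(s) ",
      paste(unique(probs$row), collapse = ", "),
      " (expected ", probs$expected[1], ", got '", probs$actual[1], "')"))
  }

  tbl <- tbl[, required]
  # map channel columns to tissue columns per the assignment
  names(tbl)[match(channel_cols, names(tbl))] <-
    paste0("intensity_", names(assignment))

  validate_psm_table(tbl, path)
  tbl
}

validate_psm_table <- function(tbl, path = "<in memory>") {
  bad_p <- which(!is.na(tbl$confidence_p) &
                   (tbl$confidence_p < 0 | tbl$confidence_p > 1))
  if (length(bad_p) > 0) {
    abort(paste0("invalid confidence_p outside [0, 1] in '", path,
                 "' at data row(s) ", paste(head(bad_p, 5), collapse = ", ")))
  }
  both <- !is.na(tbl$peptide_sequence) & !is.na(tbl$peptide_length)
  bad_len <- which(both & nchar(tbl$peptide_sequence) != tbl$peptide_length)
  if (length(bad_len) > 0) {
    abort(paste0("peptide_length disagrees with peptide_sequence in '", path,
                 "' at data row(s) ", paste(head(bad_len, 5), collapse = ", ")))
  }
  invisible(tbl)
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: tissue-labelled intensity columns are mapped
#' back to channel-labelled columns using the assignment. Missing values are
#' written as empty strings.
#'
#' @param psms A PSM tibble as returned by [read_psm_table()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @param assignment A [channel_assignment()].
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path, assignment = channel_assignment()) {
  stopifnot(inherits(assignment, "channel_assignment"))
  out <- psms[, c(psm_meta_cols, paste0("intensity_", names(assignment)))]
  names(out)[match(paste0("intensity_", names(assignment)), names(out))] <-
    paste0("intensity_", unname(assignment))
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a protein-level log2-ratio matrix
#'
#' Wide TSV with one row per protein: `protein_accession`, `gene_symbol`,
#' one `ratio_<patient>_<comparison>` column per (patient, comparison) pair
#' (comparison coded `TvN`, `P1vN`, `P2vN`), and optionally one
#' `spectra_<patient>` spectrum-count column per patient. Returned in long
#' form with one row per quantified cell; empty cells stay missing (no row).
#' Extra columns are tolerated.
#'
#' @param path Path to a TSV file.
#' @return A long tibble with columns `protein_accession`, `gene_symbol`,
#'   `patient_id`, `comparison`, `log2_ratio`, `spectrum_count`.
#' @export
read_protein_quant_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_accession = readr::col_character(),
    gene_symbol = readr::col_character(),
    .default = readr::col_double()
  ), na = "", progress = FALSE)
  if (!all(c("protein_accession", "gene_symbol") %in% names(tbl))) {
    abort(paste0("schema error in '", path,
                 "': need protein_accession and gene_symbol columns"))
  }
  dup <- tbl$protein_accession[duplicated(tbl$protein_accession)]
  if (length(dup) > 0) {
    abort(paste0("integrity error in '", path, "': duplicated accession(s) ",
                 paste(unique(dup), collapse = ", ")))
  }

  ratio_re <- "^ratio_(.+)_(TvN|P1vN|P2vN)$"
  ratio_cols <- grep(ratio_re, names(tbl), value = TRUE)
  if (length(ratio_cols) == 0) {
    abort(paste0("schema error in '", path, "': no ratio_<patient>_<comp> ",
                 "columns found"))
  }
  spectra_cols <- grep("^spectra_(.+)$", names(tbl), value = TRUE)

  long <- tbl |>
    select(all_of(c("protein_accession", "gene_symbol", ratio_cols))) |>
    pivot_longer(all_of(ratio_cols), names_to = c("patient_id", "comp_code"),
                 names_pattern = ratio_re, values_to = "log2_ratio") |>
    filter(!is.na(.data$log2_ratio)) |>
    mutate(comparison = code_to_comparison(.data$comp_code)) |>
    select(-"comp_code")

  if (length(spectra_cols) > 0) {
    counts <- tbl |>
      select(all_of(c("protein_accession", spectra_cols))) |>
      pivot_longer(all_of(spectra_cols), names_to = "patient_id",
                   names_pattern = "^spectra_(.+)$",
                   values_to = "spectrum_count") |>
      mutate(spectrum_count = as.integer(.data$spectrum_count))
    long <- left_join(long, counts,
                      by = c("protein_accession", "patient_id"))
  } else {
    long$spectrum_count <- NA_integer_
  }
  long |>
    select("protein_accession", "gene_symbol", "patient_id", "comparison",
           "log2_ratio", "spectrum_count") |>
    arrange(.data$protein_accession, .data$patient_id,
            match(.data$comparison, COMPARISONS))
}

#' Write a protein-level log2-ratio matrix
#'
#' Inverse of [read_protein_quant_table()]. Cells with no quantified ratio
#' are written as empty strings.
#'
#' @param quant A long protein quantification tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_quant_table <- function(quant, path) {
  ratios <- quant |>
    mutate(name = paste0("ratio_", .data$patient_id, "_",
                         comparison_to_code(.data$comparison))) |>
    select("protein_accession", "gene_symbol", "name", "log2_ratio") |>
    pivot_wider(names_from = "name", values_from = "log2_ratio")
  ratio_order <- with(
    expand.grid(code = unname(COMPARISON_CODES),
                patient = sort(unique(quant$patient_id)),
                stringsAsFactors = FALSE),
    paste0("ratio_", patient, "_", code))
  ratio_order <- intersect(ratio_order, names(ratios))

  wide <- ratios
  if (!all(is.na(quant$spectrum_count))) {
    counts <- quant |>
      distinct(.data$protein_accession, .data$patient_id,
               .data$spectrum_count) |>
      mutate(name = paste0("spectra_", .data$patient_id)) |>
      select("protein_accession", "name", "spectrum_count") |>
      pivot_wider(names_from = "name", values_from = "spectrum_count")
    wide <- left_join(ratios, counts, by = "protein_accession")
  }
  count_order <- intersect(paste0("spectra_", sort(unique(quant$patient_id))),
                           names(wide))
  wide <- wide |>
    select(all_of(c("protein_accession", "gene_symbol", ratio_order,
                    count_order))) |>
    arrange(.data$protein_accession)
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a transcript fold-change table
#'
#' Wide TSV with one row per gene: `gene_symbol` plus one
#' `fc_<patient>_<tissue>` column per (patient, tissue in T/P1/P2) pair
#' holding the linear fold change versus the noncancerous reference.
#' All non-missing values must be positive.
#'
#' @param path Path to a TSV file.
#' @return A long tibble `gene_symbol`, `patient_id`, `tissue`,
#'   `fold_change`.
#' @export
read_transcript_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_symbol = readr::col_character(),
    .default = readr::col_double()
  ), na = "", progress = FALSE)
  if (!"gene_symbol" %in% names(tbl)) {
    abort(paste0("schema error in '", path, "': need gene_symbol column"))
  }
  fc_re <- "^fc_(.+)_(T|P1|P2)$"
  fc_cols <- grep(fc_re, names(tbl), value = TRUE)
  if (length(fc_cols) == 0) {
    abort(paste0("schema error in '", path,
                 "': no fc_<patient>_<tissue> columns found"))
  }
  long <- tbl |>
    select(all_of(c("gene_symbol", fc_cols))) |>
    pivot_longer(all_of(fc_cols), names_to = c("patient_id", "tissue"),
                 names_pattern = fc_re, values_to = "fold_change") |>
    filter(!is.na(.data$fold_change))
  if (any(long$fold_change <= 0)) {
    abort(paste0("invalid fold change <= 0 in '", path, "'"))
  }
  arrange(long, .data$gene_symbol, .data$patient_id,
          match(.data$tissue, TISSUES))
}

#' Write a transcript fold-change table
#'
#' Inverse of [read_transcript_table()].
#'
#' @param transcripts A long transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_table <- function(transcripts, path) {
  wide <- transcripts |>
    mutate(name = paste0("fc_", .data$patient_id, "_", .data$tissue)) |>
    select("gene_symbol", "name", "fold_change") |>
    pivot_wider(names_from = "name", values_from = "fold_change")
  col_order <- with(
    expand.grid(tissue = c("T", "P1", "P2"),
                patient = sort(unique(transcripts$patient_id)),
                stringsAsFactors = FALSE),
    paste0("fc_", patient, "_", tissue))
  wide <- wide |>
    select(all_of(c("gene_symbol", intersect(col_order, names(wide))))) |>
    arrange(.data$gene_symbol)
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a consensus candidate table
#'
#' Rows are ordered deterministically (direction, then accession). When the
#' normalized quantification matrix is supplied, per-(patient, comparison)
#' log2 ratios are appended as provenance columns.
#'
#' @param candidates A candidate tibble from [cross_patient_consensus()] or
#'   [transcript_concordance()].
#' @param path Output path.
#' @param quant Optional long protein quantification tibble for provenance
#'   ratio columns.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path, quant = NULL) {
  out <- candidates
  if (!is.null(quant) && nrow(out) > 0) {
    ratios <- quant |>
      filter(.data$protein_accession %in% out$protein_accession) |>
      mutate(name = paste0("ratio_", .data$patient_id, "_",
                           comparison_to_code(.data$comparison))) |>
      select("protein_accession", "name", "log2_ratio") |>
      pivot_wider(names_from = "name", values_from = "log2_ratio")
    out <- left_join(out, ratios, by = "protein_accession")
  }
  out <- arrange(out, .data$direction, .data$protein_accession)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read back a consensus candidate table
#'
#' @param path Path to a TSV written by [write_candidate_table()].
#' @return A candidate tibble.
#' @export
read_candidate_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_accession = readr::col_character(),
    gene_symbol = readr::col_character(),
    direction = readr::col_character(),
    .default = readr::col_guess()
  ), na = "", progress = FALSE)
  if ("n_supporting_patients" %in% names(tbl)) {
    tbl$n_supporting_patients <- as.integer(tbl$n_supporting_patients)
  }
  if ("n_concordant_patients" %in% names(tbl)) {
    tbl$n_concordant_patients <- as.integer(tbl$n_concordant_patients)
  }
  tbl
}
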