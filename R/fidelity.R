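# PDX-fidelity and cohort-structure metrics: how faithfully xenograft
# proteomes preserve the primary tumor's profile.

quant_to_wide <- function(quant) {
  wide <- quant |>
    mutate(col = column_key(.data$patient_id, .data$comparison)) |>
    select("protein_accession", "col", "log2_ratio") |>
    pivot_wider(names_from = "col", values_from = "log2_ratio") |>
    arrange(.data$protein_accession)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$protein_accession
  # deterministic column order: patient, then comparison
  keys <- distinct(quant, .data$patient_id, .data$comparison) |>
    arrange(.data$patient_id, match(.data$comparison, COMPARISONS))
  mat[, column_key(keys$patient_id, keys$comparison), drop = FALSE]
}

#' Pairwise correlation of proteome profiles
#'
#' Pearson correlation between pairs of (patient, comparison) ratio
#' columns, computed on the proteins quantified in both columns. Pairs
#' sharing fewer than `min_shared` proteins are reported as skipped with a
#' warning. By default all within-patient comparison pairs are tested
#' (T/N vs P1/N, T/N vs P2/N, P1/N vs P2/N), the level at which PDX
#' fidelity is assessed.
#'
#' @param quant A long protein quantification tibble.
#' @param pairs Optional tibble `patient_a`, `comparison_a`, `patient_b`,
#'   `comparison_b`; default all within-patient comparison pairs.
#' @param min_shared Minimum shared proteins to report a correlation
#'   (default 3).
#' @return A tibble with the pair identifiers, `r`, `p`, `n_shared`,
#'   `skipped`.
#' @export
pairwise_profile_correlation <- function(quant, pairs = NULL,
                                         min_shared = 3) {
  if (is.null(pairs)) {
    patients <- sort(unique(quant$patient_id))
    combos <- utils::combn(COMPARISONS, 2)
    pairs <- tidyr::expand_grid(
      patient = patients, i = seq_len(ncol(combos))) |>
      mutate(patient_a = .data$patient, patient_b = .data$patient,
             comparison_a = combos[1, .data$i],
             comparison_b = combos[2, .data$i]) |>
      select("patient_a", "comparison_a", "patient_b", "comparison_b")
  }
  mat <- quant_to_wide(quant)
  res <- purrr::pmap(pairs, function(patient_a, comparison_a,
                                     patient_b, comparison_b) {
    a <- mat[, column_key(patient_a, comparison_a)]
    b <- mat[, column_key(patient_b, comparison_b)]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_shared) {
      warn(paste0("pair ", column_key(patient_a, comparison_a), " vs ",
                  column_key(patient_b, comparison_b), " shares ", sum(ok),
                  " proteins (< ", min_shared, "); skipped"))
      return(tibble(patient_a = patient_a, comparison_a = comparison_a,
                    patient_b = patient_b, comparison_b = comparison_b,
                    r = NA_real_, p = NA_real_, n_shared = sum(ok),
                    skipped = TRUE))
    }
    ct <- cor.test(a[ok], b[ok], method = "pearson")
    tibble(patient_a = patient_a, comparison_a = comparison_a,
           patient_b = patient_b, comparison_b = comparison_b,
           r = unname(ct$estimate), p = ct$p.value, n_shared = sum(ok),
           skipped = FALSE)
  })
  bind_rows(res)
}

#' Quantification coverage across patient groups
#'
#' Counts proteins quantified (at least one non-missing ratio) in exactly
#' m of the n patient groups, m = 1..n. In the study this histogram is the
#' union-coverage profile: ~46% of the quantifiable union was measured in
#' all five groups.
#'
#' @param quant A long protein quantification tibble.
#' @param n_patients Number of patient groups; defaults to the number
#'   observed.
#' @return A tibble `n_patient_groups` (1..n), `n_proteins`, with attribute
#'   `total` = number of distinct quantified proteins.
#' @export
quantification_coverage <- function(quant, n_patients = NULL) {
  quant_ok <- filter(quant, !is.na(.data$log2_ratio))
  n <- n_patients %||% n_distinct(quant_ok$patient_id)
  per_protein <- quant_ok |>
    group_by(.data$protein_accession) |>
    summarize(m = n_distinct(.data$patient_id), .groups = "drop")
  counts <- tibble(n_patient_groups = seq_len(n)) |>
    left_join(count(per_protein, .data$m), by = c(n_patient_groups = "m")) |>
    mutate(n_proteins = coalesce(.data$n, 0L)) |>
    select("n_patient_groups", "n_proteins")
  attr(counts, "total") <- nrow(per_protein)
  counts
}

select_profile_matrix <- function(quant, min_patients, imputation) {
  per_protein <- quant |>
    filter(!is.na(.data$log2_ratio)) |>
    group_by(.data$protein_accession) |>
    summarize(m = n_distinct(.data$patient_id), .groups = "drop")
  keep <- per_protein$protein_accession[per_protein$m >= min_patients]
  mat <- quant_to_wide(filter(quant, .data$protein_accession %in% keep))
  if (imputation == "complete") {
    mat <- mat[complete.cases(mat), , drop = FALSE]
  } else {
    for (j in seq_len(ncol(mat))) {
      nas <- is.na(mat[, j])
      mat[nas, j] <- mean(mat[, j], na.rm = TRUE)
    }
  }
  mat
}

#' Principal component analysis of proteome profiles
#'
#' PCA over the (patient, comparison) ratio columns (columns are the
#' observations). Proteins are restricted to those quantified in at least
#' `min_patients` patient groups (mirroring a minimum-analyses selection of
#' 4 of 5) and then to complete cases, or mean-imputed. Loadings follow a
#' fixed sign convention (the largest-magnitude element of each loading
#' vector is positive), making scores reproducible.
#'
#' @param quant A long protein quantification tibble.
#' @param n_components Number of components to return (default 3).
#' @param min_patients Minimum patient groups a protein must be quantified
#'   in (default 4).
#' @param imputation `"complete"` (complete-case proteins, default) or
#'   `"mean"` (column-mean imputation).
#' @return A list of class `pca_profiles`: `scores` (tibble patient_id,
#'   comparison, PC columns), `loadings` (tibble protein_accession, PC
#'   columns), `variance_explained` (percent per component, all
#'   components).
#' @export
pca_profiles <- function(quant, n_components = 3, min_patients = 4,
                         imputation = c("complete", "mean")) {
  imputation <- match.arg(imputation)
  mat <- select_profile_matrix(quant, min_patients, imputation)
  if (ncol(mat) < 2) abort("PCA needs >= 2 (patient, comparison) columns")
  x <- t(mat)  # observations = columns of the quant matrix
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  if (n_components > rank) {
    abort(paste0("n_components = ", n_components, " exceeds rank ", rank))
  }
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scr <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scr[, j] <- -scr[, j]
    }
  }
  key_re <- "^(.*)_(TvN|P1vN|P2vN)$"
  scores <- bind_cols(
    tibble(patient_id = sub(key_re, "\\1", rownames(scr)),
           comparison = code_to_comparison(sub(key_re, "\\2",
                                               rownames(scr)))),
    as_tibble(scr))
  loadings <- bind_cols(tibble(protein_accession = rownames(rot)),
                        as_tibble(rot))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve),
            class = "pca_profiles")
}

#' @export
print.pca_profiles <- function(x, ...) {
  cat("PCA of proteome profiles:", nrow(x$scores), "profiles,",
      nrow(x$loadings), "proteins\n")
  ve <- x$variance_explained[seq_len(min(3, length(x$variance_explained)))]
  cat("  variance explained (%):", paste(sprintf("%.1f", ve),
                                         collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of proteome profiles
#'
#' Agglomerative clustering of the (patient, comparison) columns using
#' 1 - Pearson correlation distance and average linkage, on the
#' complete-case protein subset after the minimum-patients selection. In
#' the study design, profiles cluster by patient: each patient's T, P1 and
#' P2 tissues group together.
#'
#' @param quant A long protein quantification tibble.
#' @param linkage Linkage method (default `"average"`).
#' @param min_patients Minimum patient groups a protein must be quantified
#'   in (default 4).
#' @return A list of class `profile_dendrogram`: `hclust`, `phylo`
#'   (an [ape] tree) and `newick` (serialized string). Leaves are labelled
#'   `<patient>_<comparison code>`.
#' @export
hierarchical_cluster <- function(quant, linkage = "average",
                                 min_patients = 4) {
  mat <- select_profile_matrix(quant, min_patients, "complete")
  if (ncol(mat) < 2) {
    abort("hierarchical clustering needs >= 2 (patient, comparison) columns")
  }
  d <- as.dist(1 - cor(mat, method = "pearson"))
  hc <- hclust(d, method = linkage)
  phylo <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phylo,
                 newick = ape::write.tree(phylo)),
            class = "profile_dendrogram")
}

#' @export
print.profile_dendrogram <- function(x, ...) {
  cat("Average-linkage clustering of", length(x$hclust$labels),
      "proteome profiles (1 - Pearson r distance)\n")
  cat(" ", x$newick, "\n")
  invisible(x)
}
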