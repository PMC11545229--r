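#' Synthetic cohort settings
#'
#' Defines the generative model of a seeded synthetic iTRAQ cohort:
#' a union of proteins with heterogeneous spectral depth (lognormal latent
#' abundance; per-patient PSM counts Poisson around it, detection = at
#' least one PSM), per-(patient, comparison) null log2-ratio distributions
#' with slightly negative means, a protein-specific patient effect shared
#' across the three tumor comparisons (reproducing clustering by patient),
#' spiked truly-dysregulated proteins whose log2 shift is conserved across
#' T/P1/P2 with attenuation per PDX generation, keratin decoys, a small
#' fraction of quality-failing PSMs exercising the identification filter,
#' and matched transcript fold changes with tunable concordance
#' probability.
#'
#' @param n_patients Number of patient groups (default 5).
#' @param patient_ids Patient identifiers; defaults to the study-style ids
#'   "06", "29", "34", "44", "48" for five patients.
#' @param n_proteins_union Size of the protein union pool (default 6000).
#' @param depth_meanlog,depth_sdlog Lognormal parameters of the per-protein
#'   spectral depth, calibrated so ~46% of the quantified union is present
#'   in all five groups with ~6 spectra per quantified protein
#'   (defaults 1.125 and 0.95).
#' @param null_mean_range,null_sd_range Uniform ranges for the per-column
#'   null log2-ratio mean and SD (defaults \[-0.26, -0.05\] and
#'   \[0.77, 1.17\]).
#' @param n_spiked_up,n_spiked_down Numbers of truly up-/down-regulated
#'   proteins (defaults 60 and 200).
#' @param effect_size_range Spiked log2-shift magnitude as a multiple of
#'   the column SD (default uniform \[1.2, 2.5\]).
#' @param generation_attenuation Multiplicative attenuation of the spiked
#'   effect per PDX generation (default 0.9: T carries the full shift,
#'   P1 90%, P2 81%).
#' @param spike_expression_prob Probability that a spiked protein expresses
#'   its shift in a given patient (default 1).
#' @param conservation_noise_sd SD (in column-SD units) of the
#'   patient-level jitter of the spiked shift; the jitter is shared across
#'   the three generations of one patient's tumor, so conservation noise
#'   acts between patients while attenuation acts between generations
#'   (default 0.15).
#' @param spectrum_noise_sd SD of the additive log2 noise per spectrum
#'   (default 0.3).
#' @param patient_effect_sd SD of the protein-specific shift shared by a
#'   patient's three comparisons (default 0.6).
#' @param n_keratins Number of keratin decoy proteins (default 20).
#' @param frac_short_peptides,frac_low_confidence Fractions of PSMs failing
#'   the peptide-length and confidence filters (defaults 0.02 and 0.03).
#' @param transcript_concordance_prob_spiked,transcript_concordance_prob_null
#'   Probability that a spiked / null gene is transcript-concordant
#'   (defaults 0.8 and 0.05).
#' @param transcript_fc_sdlog2 SD (log2) of non-concordant fold changes
#'   around 1 (default 0.5).
#' @param concordant_fc_meanlog2,concordant_fc_sdlog2 Log2 mean magnitude
#'   and SD of concordant fold changes (defaults 1.8 and 0.35).
#' @param n_rna_patients Number of patient groups with transcript data
#'   (default 4, as RNA profiling typically covers a cohort subset).
#' @param base_log2_intensity,base_log2_intensity_sd Location/spread of the
#'   reference-channel log2 intensity (defaults 10 and 1.2).
#' @param seed Integer seed; the same seed yields identical cohorts.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 5,
                              patient_ids = NULL,
                              n_proteins_union = 6000,
                              depth_meanlog = 1.125,
                              depth_sdlog = 0.95,
                              null_mean_range = c(-0.26, -0.05),
                              null_sd_range = c(0.77, 1.17),
                              n_spiked_up = 60,
                              n_spiked_down = 200,
                              effect_size_range = c(1.2, 2.5),
                              generation_attenuation = 0.9,
                              spike_expression_prob = 1,
                              conservation_noise_sd = 0.15,
                              spectrum_noise_sd = 0.3,
                              patient_effect_sd = 0.6,
                              n_keratins = 20,
                              frac_short_peptides = 0.02,
                              frac_low_confidence = 0.03,
                              transcript_concordance_prob_spiked = 0.8,
                              transcript_concordance_prob_null = 0.05,
                              transcript_fc_sdlog2 = 0.5,
                              concordant_fc_meanlog2 = 1.8,
                              concordant_fc_sdlog2 = 0.35,
                              n_rna_patients = min(4, n_patients),
                              base_log2_intensity = 10,
                              base_log2_intensity_sd = 1.2,
                              seed = 1) {
  if (is.null(patient_ids)) {
    patient_ids <- if (n_patients == 5) c("06", "29", "34", "44", "48")
                   else sprintf("g%02d", seq_len(n_patients))
  }
  stopifnot(length(patient_ids) == n_patients,
            !anyDuplicated(patient_ids))
  probs <- c(spike_expression_prob, transcript_concordance_prob_spiked,
             transcript_concordance_prob_null, frac_short_peptides,
             frac_low_confidence)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (n_spiked_up + n_spiked_down >= n_proteins_union) {
    abort("spike counts must be smaller than the protein union")
  }
  stopifnot(n_rna_patients <= n_patients, generation_attenuation > 0,
            all(null_sd_range > 0), all(effect_size_range > 0))
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

random_peptides <- function(lengths) {
  pool_len <- 200000L
  pool <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       pool_len, replace = TRUE), collapse = "")
  start <- sample.int(pool_len - max(lengths), length(lengths),
                      replace = TRUE)
  substring(pool, start, start + lengths - 1L)
}

#' Simulate a matched proteome-transcriptome PDX cohort
#'
#' Generates a PSM table, a transcript fold-change table and the spiked
#' ground truth under the model described in [simulation_config()]. The
#' same seed yields identical outputs.
#'
#' @param config A [simulation_config()].
#' @return A list of class `pdx_cohort`: `psms` (PSM tibble as from
#'   [read_psm_table()]), `transcripts` (long transcript tibble), `truth`
#'   (per-protein ground truth), `columns` (the realized per-column null
#'   mean `mu0` and SD `sigma0`), and `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_proteins_union = 300,
#'                                             n_spiked_up = 10,
#'                                             n_spiked_down = 20,
#'                                             seed = 7))
#' nrow(cohort$psms)
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_u <- cfg$n_proteins_union
  n_all <- n_u + cfg$n_keratins
  patients <- cfg$patient_ids

  proteins <- tibble(
    protein_accession = c(sprintf("SIMP%05d", seq_len(n_u)),
                          if (cfg$n_keratins > 0)
                            sprintf("SIMK%03d", seq_len(cfg$n_keratins))),
    gene_symbol = c(sprintf("GENE%05d", seq_len(n_u)),
                    if (cfg$n_keratins > 0)
                      paste0("KRT", seq_len(cfg$n_keratins))),
    status = "null")
  spike_idx <- sample.int(n_u, cfg$n_spiked_up + cfg$n_spiked_down)
  proteins$status[spike_idx[seq_len(cfg$n_spiked_up)]] <- "spiked_up"
  proteins$status[spike_idx[seq_len(cfg$n_spiked_down) +
                              cfg$n_spiked_up]] <- "spiked_down"
  if (cfg$n_keratins > 0) proteins$status[(n_u + 1):n_all] <- "keratin"
  proteins$direction <- c(spiked_up = "up", spiked_down = "down")[
    proteins$status]
  proteins$effect_scale <- ifelse(
    proteins$status %in% c("spiked_up", "spiked_down"),
    runif(n_all, cfg$effect_size_range[1], cfg$effect_size_range[2]),
    NA_real_)
  proteins$lambda <- rlnorm(n_all, cfg$depth_meanlog, cfg$depth_sdlog)

  # per-(patient, comparison) null moments
  columns <- tidyr::expand_grid(patient_id = patients,
                                comparison = COMPARISONS) |>
    mutate(mu0 = runif(n(), cfg$null_mean_range[1], cfg$null_mean_range[2]),
           sigma0 = runif(n(), cfg$null_sd_range[1], cfg$null_sd_range[2]),
           generation = match(.data$comparison, COMPARISONS) - 1L)

  # per-(protein, patient) structure
  pp <- tidyr::expand_grid(idx = seq_len(n_all), patient_id = patients) |>
    mutate(
      n_psm = rpois(n(), proteins$lambda[.data$idx]),
      patient_effect = rnorm(n(), 0, cfg$patient_effect_sd),
      spike_jitter = rnorm(n(), 0, cfg$conservation_noise_sd),
      expressed = rbinom(n(), 1, cfg$spike_expression_prob) == 1) |>
    filter(.data$n_psm > 0)
  is_spiked <- proteins$status[pp$idx] %in% c("spiked_up", "spiked_down")
  pp$patient_effect[is_spiked] <- 0
  pp$expressed <- pp$expressed & is_spiked

  # per-(protein, patient, comparison) true log2 ratio
  ppc <- pp |>
    tidyr::expand_grid(comparison = COMPARISONS) |>
    left_join(columns, by = c("patient_id", "comparison"))
  status <- proteins$status[ppc$idx]
  spiked <- status %in% c("spiked_up", "spiked_down")
  sign_eff <- ifelse(status == "spiked_up", 1, -1)
  noise_var <- cfg$spectrum_noise_sd^2 / ppc$n_psm
  resid_sd_null <- sqrt(pmax(
    ppc$sigma0^2 - cfg$patient_effect_sd^2 - noise_var, 0.04))
  resid_sd_unexpr <- sqrt(pmax(ppc$sigma0^2 - noise_var, 0.04))
  # the spike jitter (tumor-level variation of the true shift) is shared by
  # the three generations of one patient's tumor; only measurement noise is
  # per spectrum
  ppc$true_log2 <- ifelse(
    spiked & ppc$expressed,
    ppc$mu0 + (sign_eff * proteins$effect_scale[ppc$idx] +
                 ppc$spike_jitter) * ppc$sigma0 *
      cfg$generation_attenuation^ppc$generation,
    ifelse(spiked,
           ppc$mu0 + rnorm(nrow(ppc), 0, resid_sd_unexpr),
           ppc$mu0 + ppc$patient_effect +
             rnorm(nrow(ppc), 0, resid_sd_null)))

  # spectrum-level table
  true_wide <- ppc |>
    select("idx", "patient_id", "comparison", "true_log2") |>
    pivot_wider(names_from = "comparison", values_from = "true_log2")
  spectra <- pp |>
    left_join(true_wide, by = c("idx", "patient_id")) |>
    tidyr::uncount(.data$n_psm)
  n_s <- nrow(spectra)

  base <- 2^rnorm(n_s, cfg$base_log2_intensity, cfg$base_log2_intensity_sd)
  psms <- tibble(
    patient_id = spectra$patient_id,
    protein_accession = proteins$protein_accession[spectra$idx],
    gene_symbol = proteins$gene_symbol[spectra$idx],
    intensity_N = base,
    intensity_T = base *
      2^(spectra[["T/N"]] + rnorm(n_s, 0, cfg$spectrum_noise_sd)),
    intensity_P1 = base *
      2^(spectra[["P1/N"]] + rnorm(n_s, 0, cfg$spectrum_noise_sd)),
    intensity_P2 = base *
      2^(spectra[["P2/N"]] + rnorm(n_s, 0, cfg$spectrum_noise_sd)))
  lengths <- sample(8:25, n_s, replace = TRUE)
  short <- runif(n_s) < cfg$frac_short_peptides
  lengths[short] <- sample(5:7, sum(short), replace = TRUE)
  psms$peptide_sequence <- random_peptides(lengths)
  psms$peptide_length <- as.integer(lengths)
  psms$confidence_p <- runif(n_s, 0, 0.0095)
  low <- runif(n_s) < cfg$frac_low_confidence
  psms$confidence_p[low] <- runif(sum(low), 0.01, 0.2)
  psms <- psms[, c(psm_meta_cols, paste0("intensity_", TISSUES))] |>
    arrange(.data$patient_id, .data$protein_accession,
            .data$peptide_sequence)

  # ground truth
  expr_by_prot <- pp |>
    group_by(.data$idx) |>
    summarize(n_patients_detected = n(),
              n_patients_expressed = sum(.data$expressed),
              expressed_patients = paste(
                sort(.data$patient_id[.data$expressed]), collapse = ","),
              .groups = "drop")
  truth <- proteins |>
    mutate(idx = row_number()) |>
    left_join(expr_by_prot, by = "idx") |>
    mutate(n_patients_detected = coalesce(.data$n_patients_detected, 0L),
           n_patients_expressed = coalesce(.data$n_patients_expressed, 0L),
           expressed_patients = coalesce(.data$expressed_patients, ""))
  spiked_p <- truth$status %in% c("spiked_up", "spiked_down")
  truth$transcript_concordant <- rbinom(
    n_all, 1, ifelse(spiked_p, cfg$transcript_concordance_prob_spiked,
                     cfg$transcript_concordance_prob_null)) == 1
  truth <- select(truth, -"idx")

  # matched transcript fold changes (union genes only, no keratins)
  rna_patients <- head(patients, cfg$n_rna_patients)
  tr_truth <- truth[seq_len(n_u), ]
  tr_sign <- ifelse(tr_truth$status == "spiked_down", -1,
                    ifelse(tr_truth$status == "spiked_up", 1,
                           sample(c(-1, 1), n_u, replace = TRUE)))
  transcripts <- tidyr::expand_grid(
    gene_idx = seq_len(n_u), patient_id = rna_patients,
    tissue = c("T", "P1", "P2")) |>
    mutate(
      gene_symbol = tr_truth$gene_symbol[.data$gene_idx],
      concordant = tr_truth$transcript_concordant[.data$gene_idx],
      fold_change = ifelse(
        .data$concordant,
        2^(tr_sign[.data$gene_idx] *
             rnorm(n(), cfg$concordant_fc_meanlog2,
                   cfg$concordant_fc_sdlog2)),
        2^rnorm(n(), 0, cfg$transcript_fc_sdlog2))) |>
    select("gene_symbol", "patient_id", "tissue", "fold_change") |>
    arrange(.data$gene_symbol, .data$patient_id,
            match(.data$tissue, TISSUES))

  attr(psms, "cohort_seed") <- cfg$seed
  attr(transcripts, "cohort_seed") <- cfg$seed
  attr(truth, "cohort_seed") <- cfg$seed
  out <- list(psms = psms, transcripts = transcripts, truth = truth,
              columns = select(columns, "patient_id", "comparison",
                               "mu0", "sigma0"),
              config = cfg)
  attr(out, "cohort_seed") <- cfg$seed
  structure(out, class = "pdx_cohort")
}

#' @export
print.pdx_cohort <- function(x, ...) {
  cat("Synthetic PDX cohort (seed", x$config$seed, "):",
      nrow(x$psms), "PSMs,", nrow(x$truth), "proteins,",
      x$config$n_patients, "patients\n")
  print(count(x$truth, .data$status))
  invisible(x)
}
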