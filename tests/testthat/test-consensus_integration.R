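# calls fixture: one patient, three proteins with distinct call patterns
patient_calls <- function(patient = "06",
                          patterns = list(
                            A = c("over", "over", "over"),
                            B = c("over", "over", "unchanged"),
                            C = c("over", "under", "under"),
                            D = c("under", "under", "under"),
                            E = c("over", "over", "not_quantified"))) {
  dplyr::bind_rows(lapply(names(patterns), function(p) {
    tibble::tibble(protein_accession = p, gene_symbol = paste0("G", p),
                   patient_id = patient,
                   comparison = c("T/N", "P1/N", "P2/N"),
                   log2_ratio = 0, label = patterns[[p]])
  }))
}

test_that("within-patient conservation needs the same call in all three tissues", {
  sets <- within_patient_consensus(patient_calls())
  expect_equal(sets$protein_accession[sets$direction == "up"], "A")
  expect_equal(sets$protein_accession[sets$direction == "down"], "D")
  # B (unchanged in P2), C (direction conflict), E (not quantified in P2)
  # are all excluded
  expect_false(any(c("B", "C", "E") %in% sets$protein_accession))
})

test_that("up and down sets never overlap within a patient", {
  calls <- withr::with_seed(9, {
    labels <- sample(c("over", "under", "unchanged", "not_quantified"),
                     3 * 200, replace = TRUE)
    tibble::tibble(
      protein_accession = rep(sprintf("P%03d", 1:200), each = 3),
      gene_symbol = "G", patient_id = "06",
      comparison = rep(c("T/N", "P1/N", "P2/N"), 200),
      log2_ratio = 0, label = labels)
  })
  sets <- within_patient_consensus(calls)
  overlap <- sets |>
    dplyr::count(patient_id, protein_accession) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(overlap), 0)
})

test_that("cross-patient consensus requires k same-direction patients", {
  per_patient <- dplyr::bind_rows(
    tibble::tibble(patient_id = c("06", "29", "34"),
                   protein_accession = "A", gene_symbol = "GA",
                   direction = "up"),
    tibble::tibble(patient_id = c("06", "29"),
                   protein_accession = "B", gene_symbol = "GB",
                   direction = "up"),
    tibble::tibble(patient_id = "34", protein_accession = "B",
                   gene_symbol = "GB", direction = "down"))
  cand <- cross_patient_consensus(per_patient, k = 3, n_patients = 5)
  expect_equal(cand$protein_accession, "A")
  expect_equal(cand$n_supporting_patients, 3L)
  expect_equal(cand$supporting_patients, "06,29,34")
  expect_false(cand$conflict)

  # k = 1 reduces to the union of per-patient sets
  all1 <- cross_patient_consensus(per_patient, k = 1, n_patients = 5)
  expect_setequal(paste(all1$protein_accession, all1$direction),
                  c("A up", "B up", "B down"))

  expect_error(cross_patient_consensus(per_patient, k = 6, n_patients = 5),
               "k")
})

test_that("a protein reaching k in both directions is flagged, not dropped", {
  per_patient <- tibble::tibble(
    patient_id = c("06", "29", "34", "44"),
    protein_accession = "X", gene_symbol = "GX",
    direction = c("up", "up", "down", "down"))
  cand <- cross_patient_consensus(per_patient, k = 2, n_patients = 5)
  expect_equal(nrow(cand), 2)
  expect_true(all(cand$conflict))
})

test_that("consensus size is monotone in k and nested in the union", {
  run <- default_run()
  within <- run$within_patient
  n_pat <- dplyr::n_distinct(run$quant$patient_id)
  sizes <- vapply(seq_len(n_pat), function(k) {
    nrow(cross_patient_consensus(within, k = k, n_patients = n_pat))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1],
               nrow(dplyr::distinct(within, protein_accession, direction)))

  cand <- run$candidates
  union_keys <- paste(within$protein_accession, within$direction)
  expect_true(all(paste(cand$protein_accession, cand$direction) %in%
                    union_keys))
  conc <- dplyr::filter(cand, transcript_concordant)
  expect_true(all(conc$protein_accession %in% cand$protein_accession))
})

test_that("transcript concordance uses strict bounds per patient and tissue", {
  cand <- tibble::tibble(
    protein_accession = c("A", "B", "C"),
    gene_symbol = c("GA", "GB", "GC"),
    direction = c("up", "up", "down"),
    n_supporting_patients = 3L, supporting_patients = "06,29,34",
    conflict = FALSE)
  patients <- c("06", "29", "34", "44")
  tr <- dplyr::bind_rows(
    # GA: clear upregulation in 3 of 4 patients, boundary 2.0 in the 4th
    tidyr::expand_grid(patient_id = patients[1:3],
                       tissue = c("T", "P1", "P2")) |>
      dplyr::mutate(gene_symbol = "GA",
                    fold_change = rep(c(2.5, 3.1, 4.0), 3)),
    tibble::tibble(gene_symbol = "GA", patient_id = "44",
                   tissue = c("T", "P1", "P2"), fold_change = 2.0),
    # GC: downregulated everywhere
    tidyr::expand_grid(patient_id = patients[1:3],
                       tissue = c("T", "P1", "P2")) |>
      dplyr::mutate(gene_symbol = "GC", fold_change = 0.4))
  out <- transcript_concordance(cand, tr, min_patients = 3)
  res <- setNames(out$transcript_concordant, out$protein_accession)
  expect_true(res[["A"]])
  expect_true(res[["C"]])
  expect_false(res[["B"]])
  expect_equal(out$rna_status[out$protein_accession == "B"], "no_rna_data")
  # the fold change of exactly 2.0 contributes no supporting patient
  expect_equal(out$n_concordant_patients[out$protein_accession == "A"], 3L)

  # at min_patients = 4 the boundary patient makes GA discordant
  strict <- transcript_concordance(cand, tr, min_patients = 4)
  expect_false(strict$transcript_concordant[
    strict$protein_accession == "A"])
})

test_that("the co-expression screen applies ratio and correlation gates", {
  set.seed(31)
  n <- 40
  anchor <- rnorm(n)
  expr <- cbind(
    ENAH = anchor,
    TWIN = anchor * 2 + 3,              # r = 1
    ANTI = -anchor,                     # r = -1
    NOIS = rnorm(n))
  ratios <- tibble::tibble(
    gene_symbol = c("TWIN", "ANTI", "NOIS"),
    tumor_ratio = c(3, 2, 3), ratio_p = 0.001)
  out <- coexpression_screen(expr, ratios)
  expect_false("ENAH" %in% out$gene_symbol)
  expect_equal(out$r[out$gene_symbol == "TWIN"], 1)
  expect_true(out$passes[out$gene_symbol == "TWIN"])
  expect_false(out$passes[out$gene_symbol == "ANTI"])

  # the tumor-ratio gate is strict: exactly 1.5 blocks a perfect correlate
  low_ratio <- dplyr::mutate(
    ratios, tumor_ratio = dplyr::if_else(gene_symbol == "TWIN", 1.5,
                                         tumor_ratio))
  out2 <- coexpression_screen(expr, low_ratio)
  expect_false(out2$passes[out2$gene_symbol == "TWIN"])

  expect_error(coexpression_screen(expr[, -1], ratios), "anchor")
})
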