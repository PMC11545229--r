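test_that("spectrum ratios are log2 of channel over reference", {
  psms <- dplyr::bind_rows(
    make_psm(intensity_N = 100, intensity_T = 200, intensity_P1 = NA,
             intensity_P2 = NA),
    make_psm(intensity_N = NA, intensity_T = 500),
    make_psm(intensity_N = 100, intensity_T = 100, intensity_P1 = 50,
             intensity_P2 = 0))
  r <- compute_spectrum_ratios(psms)
  expect_equal(r$log2_ratio[r$spectrum_id == 1], 1.0)
  # missing reference yields no ratios at all
  expect_false(2 %in% r$spectrum_id)
  r3 <- r[r$spectrum_id == 3, ]
  expect_equal(r3$log2_ratio[r3$comparison == "T/N"], 0.0)
  expect_equal(r3$log2_ratio[r3$comparison == "P1/N"], -1.0)
  # zero intensity treated as missing, never -Inf
  expect_false("P2/N" %in% r3$comparison)
  expect_true(all(is.finite(r$log2_ratio)))
})

test_that("protein aggregation matches the brute-force statistic", {
  ratios <- tibble::tibble(
    spectrum_id = 1:2, protein_accession = "A", gene_symbol = "G",
    patient_id = "06", comparison = "T/N", log2_ratio = c(0.5, 0.7))
  brute_median <- function(x) {
    s <- sort(x)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  q <- aggregate_protein_ratios(ratios)
  expect_equal(q$log2_ratio, brute_median(c(0.5, 0.7)))
  expect_equal(q$log2_ratio, 0.6)

  qm <- aggregate_protein_ratios(ratios, quant_config(aggregation = "mean"))
  expect_equal(qm$log2_ratio, sum(c(0.5, 0.7)) / 2)

  # symmetric ratios cancel
  sym <- dplyr::mutate(ratios, log2_ratio = c(-1.234, 1.234))
  expect_equal(aggregate_protein_ratios(sym)$log2_ratio, 0.0)
})

test_that("the quantifiability minimum suppresses single-spectrum proteins", {
  one <- tibble::tibble(
    spectrum_id = 1L, protein_accession = "A", gene_symbol = "G",
    patient_id = "06", comparison = "T/N", log2_ratio = 0.5)
  expect_equal(nrow(aggregate_protein_ratios(one)), 0)
  expect_equal(nrow(aggregate_protein_ratios(
    one, quant_config(min_quantifiable_spectra = 1))), 1)

  # per-patient scope: a protein with one T/N and one P1/N spectrum has two
  # quantifiable spectra overall, so both cells are kept ...
  two <- tibble::tibble(
    spectrum_id = 1:2, protein_accession = "A", gene_symbol = "G",
    patient_id = "06", comparison = c("T/N", "P1/N"),
    log2_ratio = c(0.5, 0.2))
  expect_equal(nrow(aggregate_protein_ratios(two)), 2)
  # ... but per-comparison scope drops both
  expect_equal(nrow(aggregate_protein_ratios(
    two, quant_config(count_scope = "per_comparison"))), 0)
})

test_that("aggregation is invariant to spectrum order", {
  ratios <- withr::with_seed(8, tibble::tibble(
    spectrum_id = 1:60,
    protein_accession = rep(c("A", "B", "C"), each = 20),
    gene_symbol = "G", patient_id = "06",
    comparison = rep(c("T/N", "P1/N"), 30),
    log2_ratio = rnorm(60)))
  a <- aggregate_protein_ratios(ratios)
  b <- aggregate_protein_ratios(ratios[sample(60), ])
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("median normalization centers columns and is idempotent", {
  q <- make_quant(c(1, 2, 3))
  n1 <- median_normalize(q)
  expect_equal(n1$log2_ratio, c(-1, 0, 1))

  const <- make_quant(c(4, 4, 4))
  expect_equal(median_normalize(const)$log2_ratio, c(0, 0, 0))

  # median centering leaves a skewed column's mean nonzero
  skew <- make_quant(c(-3, 0, 1))
  ns <- median_normalize(skew)
  expect_equal(ns$log2_ratio, c(-3, 0, 1))
  expect_equal(mean(ns$log2_ratio), -2 / 3)

  expect_equal(median_normalize(n1)$log2_ratio, n1$log2_ratio)

  # post-normalization median is 0 in every column
  multi <- dplyr::bind_rows(make_quant(c(2, 5, 9)),
                            make_quant(c(-4, 0, 3), comparison = "P1/N"))
  nm <- median_normalize(multi) |>
    dplyr::group_by(comparison) |>
    dplyr::summarize(med = median(log2_ratio))
  expect_true(all(abs(nm$med) < 1e-12))

  allna <- make_quant(c(NA_real_, NA_real_))
  expect_error(median_normalize(allna), "06_TvN")
})

test_that("median aggregation is unbiased for symmetric spectrum noise", {
  n_prot <- 1000
  n_spec <- 51
  delta <- 0.8
  agg <- withr::with_seed(123, {
    ratios <- tibble::tibble(
      spectrum_id = seq_len(n_prot * n_spec),
      protein_accession = rep(sprintf("P%04d", seq_len(n_prot)),
                              each = n_spec),
      gene_symbol = "G", patient_id = "06", comparison = "T/N",
      log2_ratio = delta + rnorm(n_prot * n_spec, 0, 0.3))
    aggregate_protein_ratios(ratios)
  })
  expect_equal(nrow(agg), n_prot)
  expect_lt(abs(mean(agg$log2_ratio) - delta), 0.05)
})
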