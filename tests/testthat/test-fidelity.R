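# builds a 3-comparison quant tibble for one patient from a value matrix
quant_from_matrix <- function(M, patient = "06") {
  colnames(M) <- c("T/N", "P1/N", "P2/N")[seq_len(ncol(M))]
  tibble::as_tibble(M) |>
    dplyr::mutate(protein_accession = sprintf("P%03d", dplyr::row_number()),
                  gene_symbol = protein_accession) |>
    tidyr::pivot_longer(-c(protein_accession, gene_symbol),
                        names_to = "comparison",
                        values_to = "log2_ratio") |>
    dplyr::mutate(patient_id = patient, spectrum_count = 5L,
                  n_spectra = 5L)
}

test_that("profile correlation matches the brute-force Pearson formula", {
  M <- cbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(2, 4, 6, 8))
  q <- quant_from_matrix(M)
  res <- pairwise_profile_correlation(q)
  get_r <- function(a, b) {
    res$r[res$comparison_a == a & res$comparison_b == b]
  }
  expect_equal(get_r("T/N", "P1/N"), brute_pearson(M[, 1], M[, 2]))
  expect_equal(get_r("T/N", "P1/N"), 0.8)
  # affine rescaling gives r = 1
  expect_equal(get_r("T/N", "P2/N"), 1)
  expect_true(all(res$n_shared == 4))

  # self-pair and symmetry
  self <- pairwise_profile_correlation(q, pairs = tibble::tibble(
    patient_a = "06", comparison_a = "T/N",
    patient_b = "06", comparison_b = "T/N"))
  expect_equal(self$r, 1)
  swapped <- pairwise_profile_correlation(q, pairs = tibble::tibble(
    patient_a = "06", comparison_a = "P1/N",
    patient_b = "06", comparison_b = "T/N"))
  expect_equal(swapped$r, get_r("T/N", "P1/N"))
})

test_that("pairs sharing fewer than three proteins are skipped with a warning", {
  q <- quant_from_matrix(cbind(c(1, 2, NA, NA), c(NA, 2, 3, 4), c(1, 2, 3, 4)))
  pair <- tibble::tibble(patient_a = "06", comparison_a = "T/N",
                         patient_b = "06", comparison_b = "P1/N")
  expect_warning(
    res <- pairwise_profile_correlation(q, pairs = pair),
    "skipped")
  expect_true(res$skipped)
  expect_true(is.na(res$r))
  expect_equal(res$n_shared, 1L)
  # remaining pairs are still reported when one pair is skipped
  all_pairs <- suppressWarnings(pairwise_profile_correlation(q))
  expect_equal(nrow(all_pairs), 3)
  expect_equal(sum(all_pairs$skipped), 2)
})

test_that("quantification coverage histograms proteins by patient count", {
  q <- dplyr::bind_rows(
    make_quant(c(0.1, 0.2), patient_id = "06", accessions = c("A", "B")),
    make_quant(0.3, patient_id = "29", accessions = "A"),
    make_quant(0.4, patient_id = "34", accessions = "A"))
  cov <- quantification_coverage(q, n_patients = 5)
  expect_equal(cov$n_proteins, c(1L, 0L, 1L, 0L, 0L))
  expect_equal(attr(cov, "total"), 2L)
  # invariant under column reordering
  cov2 <- quantification_coverage(q[rev(seq_len(nrow(q))), ],
                                  n_patients = 5)
  expect_equal(cov2, cov, ignore_attr = FALSE)

  empty <- quantification_coverage(q[0, ], n_patients = 3)
  expect_equal(empty$n_proteins, c(0L, 0L, 0L))
})

test_that("PCA variance shares match the covariance eigendecomposition", {
  set.seed(17)
  M <- matrix(rnorm(12), nrow = 4)  # 4 proteins x 3 profiles
  q <- quant_from_matrix(M)
  pc <- pca_profiles(q, n_components = 2, min_patients = 1)
  expect_equal(head(pc$variance_explained, 2),
               head(brute_pca_variance_shares(t(M)), 2), tolerance = 1e-8)
  expect_equal(sum(pc$variance_explained), 100)
  # variance shares are non-increasing
  expect_true(all(diff(pc$variance_explained) <= 1e-12))

  # identical columns score identically (and collapse the rank)
  M2 <- cbind(M[, 1], M[, 1], M[, 3])
  pc2 <- pca_profiles(quant_from_matrix(M2), n_components = 1,
                      min_patients = 1)
  expect_equal(pc2$scores$PC1[1], pc2$scores$PC1[2])

  expect_error(pca_profiles(quant_from_matrix(M2), n_components = 2,
                            min_patients = 1), "rank")

  # sign convention makes repeated runs identical
  pc3 <- pca_profiles(q, n_components = 2, min_patients = 1)
  expect_equal(pc3$scores, pc$scores)
})

test_that("average-linkage clustering matches the brute-force oracle", {
  set.seed(29)
  base <- rnorm(30)
  M <- cbind(a = base, b = base + rnorm(30, 0, 0.1),
             c = rnorm(30), d = -base + rnorm(30, 0, 0.3))
  q <- dplyr::bind_rows(
    quant_from_matrix(M[, 1:3], patient = "06"),
    quant_from_matrix(M[, 4, drop = FALSE], patient = "29"))
  hc <- hierarchical_cluster(q, min_patients = 1)

  D <- 1 - cor(M)
  labs <- c("06_TvN", "06_P1vN", "06_P2vN", "29_TvN")
  dimnames(D) <- list(labs, labs)
  oracle <- brute_average_linkage(D)
  expect_equal(hclust_merge_sets(hc$hclust), oracle$merges)
  expect_equal(hc$hclust$height, oracle$heights)
  # merge heights are non-decreasing and the newick names all leaves
  expect_true(all(diff(hc$hclust$height) >= 0))
  for (l in labs) expect_match(hc$newick, l, fixed = TRUE)
})

test_that("identical profiles merge first at height zero", {
  set.seed(41)
  base <- rnorm(20)
  M <- cbind(base, base, rnorm(20))
  hc <- hierarchical_cluster(quant_from_matrix(M), min_patients = 1)
  first <- hclust_merge_sets(hc$hclust)[[1]]
  expect_equal(first, c("06_P1vN", "06_TvN"))
  expect_equal(hc$hclust$height[1], 0, tolerance = 1e-12)

  one_col <- quant_from_matrix(M[, 1, drop = FALSE])
  expect_error(hierarchical_cluster(one_col, min_patients = 1), ">= 2")
})

test_that("synthetic cohorts correlate more within than between patients", {
  run <- default_run()
  patients <- unique(run$quant$patient_id)
  within <- pairwise_profile_correlation(run$quant)
  between_pairs <- tibble::tibble(
    patient_a = patients[1:4], comparison_a = "T/N",
    patient_b = patients[2:5], comparison_b = "T/N")
  between <- pairwise_profile_correlation(run$quant, pairs = between_pairs)
  expect_gt(mean(within$r), mean(between$r))
})
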