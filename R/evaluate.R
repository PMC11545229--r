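#' Evaluate candidate recovery against simulation ground truth
#'
#' Compares a consensus candidate set with the spiked truth of the cohort
#' it was derived from. Sensitivity is reported against the evaluable
#' spiked proteins -- those expressed (and, when the quantification matrix
#' is supplied, quantified) in at least `k` patient groups, i.e. the
#' proteins a k-of-n consensus design can possibly recover -- and also
#' against all spiked proteins. The false-discovery proportion (FDP) is
#' the fraction of candidates whose truth status is null or keratin. An
#' empty candidate set yields sensitivity 0 and FDP 0 with
#' `degenerate = TRUE`.
#'
#' @param candidates Candidate tibble from [cross_patient_consensus()].
#' @param truth Truth tibble from [simulate_cohort()].
#' @param quant Optional long quantification tibble of the same cohort;
#'   when given, evaluable proteins must also be quantified in >= `k`
#'   patient groups.
#' @param k Consensus threshold used to produce the candidates (default 3).
#' @return A list of class `truth_evaluation`: `summary` (one-row tibble
#'   with `sensitivity`, `sensitivity_all`, `fdp`, counts and
#'   `degenerate`) and `attrition` (per-direction counts).
#' @export
truth_evaluation <- function(candidates, truth, quant = NULL, k = 3) {
  seed_c <- attr(candidates, "cohort_seed")
  seed_t <- attr(truth, "cohort_seed")
  if (!is.null(seed_c) && !is.null(seed_t) && !identical(seed_c, seed_t)) {
    abort("candidates and truth come from different cohorts")
  }

  spiked <- filter(truth, .data$status %in% c("spiked_up", "spiked_down"))
  evaluable <- spiked$n_patients_expressed >= k
  if (!is.null(quant)) {
    q_pat <- quant |>
      filter(!is.na(.data$log2_ratio)) |>
      group_by(.data$protein_accession) |>
      summarize(nq = n_distinct(.data$patient_id), .groups = "drop")
    nq <- q_pat$nq[match(spiked$protein_accession, q_pat$protein_accession)]
    evaluable <- evaluable & coalesce(nq, 0L) >= k
  }

  hit <- paste(candidates$protein_accession, candidates$direction) |>
    unique()
  recovered <- paste(spiked$protein_accession, spiked$direction) %in% hit

  n_cand <- nrow(candidates)
  status_of <- truth$status[match(candidates$protein_accession,
                                  truth$protein_accession)]
  n_false <- sum(is.na(status_of) | status_of %in% c("null", "keratin"))
  degenerate <- n_cand == 0

  summary <- tibble(
    n_spiked = nrow(spiked),
    n_evaluable = sum(evaluable),
    n_recovered = sum(recovered & evaluable),
    sensitivity = if (sum(evaluable) == 0) 0
                  else sum(recovered & evaluable) / sum(evaluable),
    sensitivity_all = if (nrow(spiked) == 0) 0
                      else sum(recovered) / nrow(spiked),
    n_candidates = n_cand,
    n_false_candidates = n_false,
    fdp = if (degenerate) 0 else n_false / n_cand,
    degenerate = degenerate)

  attrition <- spiked |>
    mutate(evaluable = evaluable, recovered = recovered) |>
    group_by(.data$direction) |>
    summarize(n_spiked = n(),
              n_evaluable = sum(.data$evaluable),
              n_recovered = sum(.data$recovered & .data$evaluable),
              .groups = "drop")

  structure(list(summary = summary, attrition = attrition),
            class = "truth_evaluation")
}

#' @export
print.truth_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Recovery: %d/%d evaluable spiked proteins (sensitivity %.3f); FDP %.3f (%d/%d candidates)%s\n",
    s$n_recovered, s$n_evaluable, s$sensitivity, s$fdp,
    s$n_false_candidates, s$n_candidates,
    if (s$degenerate) " [empty candidate set]" else ""))
  invisible(x)
}

#' @export
glance.truth_evaluation <- function(x, ...) x$summary

#' @export
tidy.truth_evaluation <- function(x, ...) x$attrition
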