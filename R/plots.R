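# ggplot2 diagnostics. Figures mirror the standard views of an iTRAQ PDX
# study: the candidate funnel, the union-coverage histogram, and the PCA of
# proteome profiles.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_text
#'   labs theme_minimal scale_y_continuous position_dodge facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot the candidate funnel
#'
#' Bar chart of candidate counts per stage and direction, from
#' within-patient conservation (summed over patients) through consensus to
#' transcript concordance.
#'
#' @param object A `funnel_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.funnel_result <- function(object, ...) {
  stages <- c("within_patient_conserved", "cross_patient_consensus",
              "transcript_concordant")
  df <- object$funnel |>
    filter(.data$stage %in% stages, !is.na(.data$direction)) |>
    group_by(.data$stage, .data$direction) |>
    summarize(count = sum(.data$count), .groups = "drop") |>
    mutate(stage = factor(.data$stage, levels = stages))
  ggplot(df, aes(x = .data$stage, y = .data$count,
                 fill = .data$direction)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    labs(x = NULL, y = "proteins",
         title = "Candidate funnel by direction") +
    theme_minimal()
}

#' Plot quantification coverage across patient groups
#'
#' @param coverage Output of [quantification_coverage()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  total <- attr(coverage, "total") %||% sum(coverage$n_proteins)
  df <- mutate(coverage,
               pct = 100 * .data$n_proteins / max(total, 1))
  ggplot(df, aes(x = factor(.data$n_patient_groups),
                 y = .data$n_proteins)) +
    geom_col(fill = "grey35") +
    geom_text(aes(label = sprintf("%.1f%%", .data$pct)), vjust = -0.4,
              size = 3) +
    labs(x = "quantified in # patient groups", y = "proteins",
         title = sprintf("Union coverage (%d proteins)", total)) +
    theme_minimal()
}

#' Plot PCA scores of proteome profiles
#'
#' Score plot of the first two components; points are (patient,
#' comparison) profiles, colored by patient -- profiles of one patient
#' clustering together indicates PDX fidelity.
#'
#' @param object A `pca_profiles` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_profiles <- function(object, ...) {
  ve <- object$variance_explained
  ggplot(object$scores,
         aes(x = .data$PC1, y = .data$PC2, color = .data$patient_id,
             shape = .data$comparison)) +
    geom_point(size = 3) +
    labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
         y = sprintf("PC2 (%.1f%%)", ve[2]),
         title = "PCA of proteome profiles") +
    theme_minimal()
}
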