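#' Anchor-gene co-expression screen
#'
#' Screens an expression matrix for genes whose expression correlates with
#' an anchor gene (Pearson r strictly above `min_correlation` with
#' p < `max_p`) and whose tumor-versus-normal ratio strictly exceeds
#' `min_tumor_ratio` with p < `max_p`. This reproduces the downstream
#' partner screen used to nominate interactors of a candidate protein
#' (e.g. integrin subunits co-expressed with ENAH).
#'
#' Correlation p-values use the t-distribution transform of Pearson r
#' (as in [stats::cor.test()]).
#'
#' @param expr Numeric matrix or data frame, samples in rows, genes in
#'   columns (column names are gene symbols).
#' @param tumor_ratio A tibble with columns `gene_symbol`, `tumor_ratio`
#'   (linear T/N) and `ratio_p`.
#' @param anchor_gene Gene symbol of the anchor; must be a column of
#'   `expr`. The anchor itself is excluded from the output.
#' @param min_tumor_ratio Strict lower bound on the linear T/N ratio
#'   (default 1.5).
#' @param max_p Significance bound for both tests (default 0.05).
#' @param min_correlation Strict lower bound on Pearson r (default 0.3).
#' @return A tibble `gene_symbol`, `r`, `r_p`, `tumor_ratio`, `ratio_p`,
#'   `passes`, sorted by decreasing r.
#' @export
coexpression_screen <- function(expr, tumor_ratio, anchor_gene = "ENAH",
                                min_tumor_ratio = 1.5, max_p = 0.05,
                                min_correlation = 0.3) {
  stopifnot(min_correlation > 0, min_correlation < 1)
  expr <- as.matrix(expr)
  if (!anchor_gene %in% colnames(expr)) {
    abort(paste0("anchor gene '", anchor_gene,
                 "' absent from the expression matrix"))
  }
  anchor <- expr[, anchor_gene]
  genes <- setdiff(colnames(expr), anchor_gene)
  cors <- lapply(genes, function(g) {
    ct <- cor.test(anchor, expr[, g], method = "pearson")
    tibble(gene_symbol = g, r = unname(ct$estimate), r_p = ct$p.value)
  })
  out <- bind_rows(cors) |>
    left_join(select(tumor_ratio, "gene_symbol", "tumor_ratio", "ratio_p"),
              by = "gene_symbol") |>
    mutate(passes =
             coalesce(.data$tumor_ratio > min_tumor_ratio, FALSE) &
             coalesce(.data$ratio_p < max_p, FALSE) &
             .data$r > min_correlation &
             .data$r_p < max_p) |>
    arrange(desc(.data$r), .data$gene_symbol)
  out
}
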