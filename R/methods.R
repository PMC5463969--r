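#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   geom_vline labs scale_color_manual coord_flip
#' @export
ggplot2::autoplot

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients (%d paired), %d genes / %d miRNAs / %d CpG sites\n",
              x$n_patients, x$n_paired, x$n_genes, x$n_mirnas, x$n_meth_sites))
  cat(sprintf("  DE fraction %.2f; planted: %d miRNA pairs, %d methylation, %d CNA, %d key genes\n",
              x$frac_de_genes, x$planted_mirna_pairs, x$planted_meth_genes,
              x$planted_cna_genes, x$n_key_genes))
  cat(sprintf("  effect %.2f log2 units, noise sd %.2f, PPI edge prob %.3f, seed %d\n",
              x$effect_log2fc, x$noise_sd, x$ppi_edge_prob, x$seed))
  invisible(x)
}

#' @export
print.omx_cohort <- function(x, ...) {
  cat("<omx_cohort>\n")
  cat(sprintf("  expression: %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression) - 1))
  cat(sprintf("  miRNA: %d features; methylation: %d sites; %d segments; %d PPI edges\n",
              nrow(x$mirna), nrow(x$methylation), nrow(x$segments),
              nrow(x$ppi_edges)))
  invisible(x)
}

#' Tidy and summarize a differential table
#'
#' `tidy()` returns the per-feature table as a plain tibble; `glance()`
#' returns a one-row model summary with the number of pairs, the estimated
#' prior degrees of freedom and variance of the empirical-Bayes fit, and
#' the up/down counts.
#'
#' @param x A `omx_differential` table from [paired_moderated_test()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.omx_differential <- function(x, ...) {
  as_tibble(unclass_omx(x))
}

#' @rdname tidy.omx_differential
#' @export
glance.omx_differential <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(n_features = nrow(x), n_pairs = fit$n_pairs,
         df_residual = fit$df_residual, df_prior = fit$df_prior,
         var_prior = fit$var_prior, n_up = sum(x$status == "up"),
         n_down = sum(x$status == "down"))
}

unclass_omx <- function(x) {
  attr(x, "fit") <- NULL
  class(x) <- setdiff(class(x), c("omx_differential", "omx_centrality"))
  x
}

#' Volcano plot of a differential table
#'
#' @param object A `omx_differential` table (ideally after
#'   [classify_differential()]).
#' @param fc_min,p_max Thresholds drawn as guide lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.omx_differential <- function(object, fc_min = 2, p_max = 0.01, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$log2fc, y = -log10(pmax(.data$p_adj, 1e-300)),
                 color = .data$status)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)), linetype = 2) +
    geom_hline(yintercept = -log10(p_max), linetype = 2) +
    scale_color_manual(values = c(up = "#c0392b", down = "#2980b9",
                                  ns = "grey60")) +
    labs(x = "log2 fold change (tumor - normal)",
         y = "-log10 adjusted p", color = NULL)
}

#' Centrality scatter plot
#'
#' Degree against betweenness, point size by closeness; a quick view of
#' which nodes dominate a subnetwork topologically.
#'
#' @param object A `omx_centrality` table from [centralities()].
#' @param highlight Optional gene ids to color (e.g. candidate genes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.omx_centrality <- function(object, highlight = NULL, ...) {
  df <- as_tibble(unclass_omx(object))
  df$highlighted <- df$gene_id %in% (highlight %||% character(0))
  ggplot(df, aes(x = .data$degree, y = .data$betweenness,
                 size = .data$closeness, color = .data$highlighted)) +
    geom_point(alpha = 0.7) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "#c0392b"),
                       guide = "none") +
    labs(x = "degree", y = "betweenness", size = "closeness")
}

#' Tidy and summarize candidate gene sets
#'
#' `tidy()` stacks the three candidate sets into one long tibble with a
#' `set` column; `glance()` reports the set sizes and Venn overlap counts.
#'
#' @param x An `omx_candidates` object from [candidate_gene_sets()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.omx_candidates <- function(x, ...) {
  bind_rows(
    mutate(select(x$mirna, "gene_id", dplyr::any_of(c("direction", "n_mirnas"))),
           set = "mirna"),
    mutate(select(x$methylation, "gene_id",
                  dplyr::any_of(c("direction", "methylation"))),
           set = "methylation"),
    mutate(select(x$cna, "gene_id", dplyr::any_of(c("direction", "state", "r"))),
           set = "cna")) |>
    select("gene_id", "set", dplyr::everything())
}

#' @rdname tidy.omx_candidates
#' @export
glance.omx_candidates <- function(x, ...) {
  ov <- overlap_analysis(x)
  tibble(n_mirna = nrow(x$mirna), n_methylation = nrow(x$methylation),
         n_cna = nrow(x$cna), n_two_or_more = length(ov$in_two_or_more),
         n_triple = length(ov$triple))
}

#' Bar chart of candidate-set Venn regions
#'
#' @param sets An `omx_candidates` object.
#' @return A ggplot object.
#' @export
plot_overlap_regions <- function(sets) {
  ov <- overlap_analysis(sets)
  ggplot(ov$regions, aes(x = .data$region, y = .data$n)) +
    geom_col(fill = "#34495e") +
    coord_flip() +
    labs(x = NULL, y = "genes in region")
}
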