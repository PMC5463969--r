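#' Keep miRNA-target pairs with sufficient prediction support
#'
#' Retains (miRNA, gene) pairs predicted by at least `min_algorithms`
#' target-prediction algorithms (boundary included).
#'
#' @param targets Target map tibble (`mirna_id`, `gene_id`, `n_algorithms`).
#' @param min_algorithms Minimum algorithm support, default 3.
#' @return The filtered target map.
#' @export
filter_targets <- function(targets, min_algorithms = 3) {
  targets <- validate_target_map(targets)
  filter(targets, .data$n_algorithms >= min_algorithms)
}

#' Direction-aware miRNA filter of differentially expressed genes
#'
#' Keeps target pairs in which an up-regulated miRNA targets a
#' down-regulated gene or a down-regulated miRNA targets an up-regulated
#' gene; both sides must be differentially expressed. The miRNA-controlled
#' candidate set is every gene appearing in at least one kept pair, with
#' its supporting miRNAs collected.
#'
#' @param gene_de,mirna_de Classified differential tables
#'   ([classify_differential()]).
#' @param targets A (already support-filtered) target map.
#' @return List with `pairs` (tibble `mirna_id`, `gene_id`, `mirna_status`,
#'   `gene_status`) and `genes` (tibble `gene_id`, `direction`, `mirnas`,
#'   `n_mirnas`).
#' @export
mirna_bimodal_filter <- function(gene_de, mirna_de, targets) {
  assert_columns(gene_de, c("feature_id", "status"), "gene differential table")
  assert_columns(mirna_de, c("feature_id", "status"), "miRNA differential table")
  targets <- validate_target_map(targets)
  pairs <- targets |>
    inner_join(select(mirna_de, mirna_id = "feature_id", mirna_status = "status"),
               by = "mirna_id") |>
    inner_join(select(gene_de, gene_id = "feature_id", gene_status = "status"),
               by = "gene_id") |>
    filter((.data$mirna_status == "up" & .data$gene_status == "down") |
             (.data$mirna_status == "down" & .data$gene_status == "up")) |>
    select("mirna_id", "gene_id", "mirna_status", "gene_status")
  genes <- pairs |>
    group_by(.data$gene_id) |>
    summarise(direction = first(.data$gene_status),
              mirnas = paste(sort(.data$mirna_id), collapse = ","),
              n_mirnas = dplyr::n_distinct(.data$mirna_id), .groups = "drop")
  list(pairs = pairs, genes = genes)
}

#' Pearson correlation between paired features of two omics matrices
#'
#' For each requested (id_a, id_b) pair, the Pearson correlation across the
#' selected common samples, with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs where either vector has zero variance get `r = NA` (undefined) and
#' are meant to be excluded downstream; their count is reported as a
#' message.
#'
#' @param pairs Tibble with columns `id_a`, `id_b`.
#' @param matrix_a,matrix_b Wide omics tibbles holding the `id_a` and
#'   `id_b` features respectively.
#' @param samples Sample ids to use; default is all samples common to both
#'   matrices. At least 3 are required.
#' @return Tibble `id_a`, `id_b`, `r`, `p`, `n`.
#' @export
correlate_features <- function(pairs, matrix_a, matrix_b, samples = NULL) {
  assert_columns(pairs, c("id_a", "id_b"), "pair table")
  ma <- omx_as_matrix(matrix_a)
  mb <- omx_as_matrix(matrix_b)
  samples <- samples %||% intersect(colnames(ma), colnames(mb))
  if (length(samples) < 3) abort("correlation needs at least 3 common samples")
  missing_a <- setdiff(pairs$id_a, rownames(ma))
  missing_b <- setdiff(pairs$id_b, rownames(mb))
  if (length(missing_a) > 0 || length(missing_b) > 0) {
    abort("pair table references features absent from the matrices")
  }
  va <- ma[pairs$id_a, samples, drop = FALSE]
  vb <- mb[pairs$id_b, samples, drop = FALSE]
  n <- length(samples)
  ca <- va - rowMeans(va)
  cb <- vb - rowMeans(vb)
  sa <- sqrt(rowSums(ca^2))
  sb <- sqrt(rowSums(cb^2))
  r <- rowSums(ca * cb) / (sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[is.finite(r) & abs(r) == 1] <- 0
  n_undef <- sum(!is.finite(r))
  if (n_undef > 0) {
    inform(sprintf("%d pair(s) with zero-variance vectors: correlation undefined", n_undef))
  }
  tibble(id_a = pairs$id_a, id_b = pairs$id_b, r = unname(r), p = unname(p), n = n)
}

#' Keep functionally anti-correlated miRNA-gene pairs
#'
#' Retains correlation records with `r < r_max` and `p < p_max` (both
#' strict); undefined correlations are dropped.
#'
#' @param records Correlation tibble from [correlate_features()].
#' @param r_max Correlation ceiling, default -0.1.
#' @param p_max p-value threshold, default 0.05.
#' @return The filtered records.
#' @export
functional_pairs <- function(records, r_max = -0.1, p_max = 0.05) {
  assert_columns(records, c("id_a", "id_b", "r", "p"), "correlation records")
  filter(records, is.finite(.data$r), .data$r < r_max, .data$p < p_max)
}

#' Direction-aware methylation filter of differentially expressed genes
#'
#' Keeps genes that are over-expressed and hypomethylated or
#' under-expressed and hypermethylated; both the expression and the
#' gene-level methylation table must classify the gene as differential.
#'
#' @param gene_de Classified expression differential table.
#' @param meth_de Classified gene-level methylation differential table
#'   (from [aggregate_probes_to_genes()] + [paired_moderated_test()]).
#' @return Tibble `gene_id`, `direction` (expression), `methylation`
#'   (`hyper`/`hypo`).
#' @export
methylation_bimodal_filter <- function(gene_de, meth_de) {
  assert_columns(gene_de, c("feature_id", "status"), "gene differential table")
  assert_columns(meth_de, c("feature_id", "status"), "methylation differential table")
  inner_join(
    select(gene_de, gene_id = "feature_id", direction = "status"),
    select(meth_de, gene_id = "feature_id", meth_status = "status"),
    by = "gene_id") |>
    filter((.data$direction == "up" & .data$meth_status == "down") |
             (.data$direction == "down" & .data$meth_status == "up")) |>
    mutate(methylation = ifelse(.data$meth_status == "up", "hyper", "hypo")) |>
    select("gene_id", "direction", "methylation")
}

#' Direction-aware copy-number filter of differentially expressed genes
#'
#' Keeps genes that are over-expressed and recurrently amplified or
#' under-expressed and recurrently deleted, and whose tumor expression is
#' positively correlated with the gene's copy-number log2 ratio
#' (`r > r_min`, `p < p_max`).
#'
#' @param gene_de Classified expression differential table.
#' @param recurrent Recurrent-gene tibble from [recurrent_cna_genes()].
#' @param expr Wide expression tibble.
#' @param ratios Long gene-by-sample ratio tibble from
#'   [map_segments_to_genes()] (tumor samples).
#' @param r_min Correlation floor (strict), default 0.5.
#' @param p_max p-value threshold (strict), default 0.05.
#' @return Tibble `gene_id`, `direction`, `state`, `r`, `p`, `n`.
#' @export
cna_bimodal_filter <- function(gene_de, recurrent, expr, ratios,
                               r_min = 0.5, p_max = 0.05) {
  assert_columns(gene_de, c("feature_id", "status"), "gene differential table")
  assert_columns(recurrent, c("gene_id", "state"), "recurrent-gene table")
  assert_columns(ratios, c("gene_id", "sample_id", "log2_ratio"), "ratio table")
  concordant <- inner_join(
    select(gene_de, gene_id = "feature_id", direction = "status"),
    select(recurrent, "gene_id", "state"), by = "gene_id") |>
    filter((.data$direction == "up" & .data$state == "amp") |
             (.data$direction == "down" & .data$state == "del"))
  if (nrow(concordant) == 0) {
    return(tibble(gene_id = character(0), direction = character(0),
                  state = character(0), r = double(0), p = double(0),
                  n = integer(0)))
  }
  m <- omx_as_matrix(expr)
  ratio_samples <- unique(ratios$sample_id)
  common <- intersect(colnames(m), ratio_samples)
  if (length(common) < 3) abort("need at least 3 samples shared between expression and ratios")
  ratio_wide <- ratios |>
    filter(.data$gene_id %in% concordant$gene_id, .data$sample_id %in% common) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "log2_ratio")
  rw <- as.matrix(ratio_wide[, -1])
  rownames(rw) <- ratio_wide$gene_id
  rec <- purrr::map_dfr(concordant$gene_id, function(g) {
    if (!g %in% rownames(rw) || !g %in% rownames(m)) {
      return(tibble(gene_id = g, r = NA_real_, p = NA_real_, n = 0L))
    }
    x <- m[g, colnames(rw)]
    y <- rw[g, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || var(x[ok]) == 0 || var(y[ok]) == 0) {
      return(tibble(gene_id = g, r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    r <- cor(x[ok], y[ok])
    tt <- r * sqrt((sum(ok) - 2) / max(1 - r^2, .Machine$double.eps))
    tibble(gene_id = g, r = r, p = 2 * pt(-abs(tt), sum(ok) - 2), n = sum(ok))
  })
  concordant |>
    inner_join(rec, by = "gene_id") |>
    filter(is.finite(.data$r), .data$r > r_min, .data$p < p_max)
}

#' Bundle the three regulator-controlled candidate gene sets
#'
#' @param mirna Candidate tibble from [mirna_bimodal_filter()] (`$genes`).
#' @param methylation Candidate tibble from [methylation_bimodal_filter()].
#' @param cna Candidate tibble from [cna_bimodal_filter()].
#' @return An `omx_candidates` list with elements `mirna`, `methylation`,
#'   `cna`.
#' @export
candidate_gene_sets <- function(mirna, methylation, cna) {
  for (s in list(mirna, methylation, cna)) assert_columns(s, "gene_id", "candidate set")
  structure(list(mirna = as_tibble(mirna), methylation = as_tibble(methylation),
                 cna = as_tibble(cna)), class = "omx_candidates")
}

#' Overlap structure of the three candidate sets
#'
#' Reports all seven Venn regions over the miRNA-, methylation- and
#' CNA-controlled candidate sets, the genes common to at least two sets,
#' and the triple intersection.
#'
#' @param sets An `omx_candidates` object from [candidate_gene_sets()].
#' @return List with `regions` (tibble `region`, `n`, `genes`),
#'   `in_two_or_more` and `triple` (character vectors).
#' @export
overlap_analysis <- function(sets) {
  stopifnot(inherits(sets, "omx_candidates"))
  a <- unique(sets$mirna$gene_id)
  b <- unique(sets$methylation$gene_id)
  c_ <- unique(sets$cna$gene_id)
  all_ids <- sort(unique(c(a, b, c_)))
  member <- tibble(gene_id = all_ids,
                   in_mirna = all_ids %in% a,
                   in_meth = all_ids %in% b,
                   in_cna = all_ids %in% c_)
  key <- paste0(ifelse(member$in_mirna, "m", ""),
                ifelse(member$in_meth, "M", ""),
                ifelse(member$in_cna, "C", ""))
  region_names <- c(m = "mirna_only", M = "methylation_only", C = "cna_only",
                    mM = "mirna_methylation", mC = "mirna_cna",
                    MC = "methylation_cna", mMC = "all_three")
  regions <- purrr::imap_dfr(region_names, function(nm, k) {
    g <- member$gene_id[key == k]
    tibble(region = nm, n = length(g), genes = list(sort(g)))
  })
  n_sets <- member$in_mirna + member$in_meth + member$in_cna
  list(regions = regions,
       in_two_or_more = sort(member$gene_id[n_sets >= 2]),
       triple = sort(member$gene_id[n_sets == 3]))
}
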