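#' Map copy-number segments onto genes
#'
#' Assigns every gene, in every sample, the `seg_mean` (log2 copy-number
#' ratio) of the overlapping segment. Genes overlapping several segments
#' take the segment with the largest overlap length; ties break to the
#' segment with the earlier start. Genes with no overlapping segment are
#' `NA` for that sample. SEG coordinates are 1-based inclusive and the gene
#' table is 0-based half-open; both are handled internally on a common
#' half-open scale.
#'
#' @param segments Segment tibble (`sample_id`, `chromosome`, `start`,
#'   `end`, `seg_mean`).
#' @param genes BED-like gene tibble (`chrom`, `start`, `end`, `gene_id`).
#' @return A long tibble (`gene_id`, `sample_id`, `log2_ratio`) with one
#'   row per gene/sample cell that has coverage.
#' @export
map_segments_to_genes <- function(segments, genes) {
  segments <- validate_seg(segments)
  assert_columns(genes, c("chrom", "start", "end", "gene_id"), "gene table")
  chrom_gap <- setdiff(unique(genes$chrom), unique(segments$chromosome))
  if (length(chrom_gap) > 0) {
    inform(sprintf("no segments on %d chromosome(s) present in the gene table (%s): affected genes are missing",
                   length(chrom_gap), paste(head(chrom_gap, 3), collapse = ", ")))
  }
  # common 1-based inclusive representation for IRanges
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  seg_gr <- GenomicRanges::GRanges(
    segments$chromosome, IRanges::IRanges(start = segments$start, end = segments$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  overlap <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gene_gr)[gi], IRanges::ranges(seg_gr)[si]))
  tibble(gene_id = genes$gene_id[gi],
         sample_id = segments$sample_id[si],
         log2_ratio = segments$seg_mean[si],
         overlap = overlap,
         seg_start = segments$start[si]) |>
    arrange(.data$gene_id, .data$sample_id, desc(.data$overlap), .data$seg_start) |>
    distinct(.data$gene_id, .data$sample_id, .keep_all = TRUE) |>
    select("gene_id", "sample_id", "log2_ratio")
}

#' Default log2-ratio thresholds for five-state copy-number calls
#'
#' @param homdel,hetdel,gain,amp Log2-ratio cut points (strictly ordered).
#' @return Named list with `homdel`, `hetdel`, `gain`, `amp`.
#' @export
cna_thresholds <- function(homdel = -1.3, hetdel = -0.3, gain = 0.3, amp = 0.9) {
  th <- list(homdel = homdel, hetdel = hetdel, gain = gain, amp = amp)
  if (!(th$homdel < th$hetdel && th$hetdel < th$gain && th$gain < th$amp)) {
    abort("thresholds must satisfy homdel < hetdel < gain < amp")
  }
  th
}

#' Five-state copy-number calls per gene and sample
#'
#' `homdel` if the ratio is at or below the homozygous-deletion threshold,
#' `hetdel` at or below the heterozygous one, `amp` at or above the
#' amplification threshold (boundary included on the extreme side), `gain`
#' at or above the gain threshold but below `amp`, `diploid` otherwise.
#' Only `amp` and `homdel` count as significant changes in a sample.
#'
#' @param ratios Long tibble from [map_segments_to_genes()].
#' @param thresholds A [cna_thresholds()] list.
#' @return The input with `state` and logical `significant` columns.
#' @export
call_cna_states <- function(ratios, thresholds = cna_thresholds()) {
  assert_columns(ratios, c("gene_id", "sample_id", "log2_ratio"), "ratio table")
  th <- do.call(cna_thresholds, thresholds)
  r <- ratios$log2_ratio
  state <- dplyr::case_when(
    r <= th$homdel ~ "homdel",
    r <= th$hetdel ~ "hetdel",
    r >= th$amp ~ "amp",
    r >= th$gain ~ "gain",
    TRUE ~ "diploid")
  mutate(ratios, state = state, significant = state %in% c("amp", "homdel"))
}

#' Recurrently amplified and deleted genes
#'
#' A desk-scale recurrence test over the call matrix: for each gene and each
#' significant state (`amp`, `homdel`), the per-gene alteration frequency is
#' compared against the cohort-wide background rate of that state with a
#' one-sided binomial tail test; p-values are BH-adjusted per state. A gene
#' is reported when `q < q_max` and its frequency exceeds the background
#' rate. When the background rate of a state is exactly zero it is floored
#' at `1 / (2 * n_samples * n_genes)` so genes carrying the state remain
#' testable.
#'
#' @param calls Call tibble from [call_cna_states()].
#' @param q_max BH-adjusted p threshold (strict), default 0.01.
#' @return Tibble (`gene_id`, `state` in `{amp, del}`, `n_altered`,
#'   `n_samples`, `frequency`, `background`, `p`, `q`) of reported genes.
#' @export
recurrent_cna_genes <- function(calls, q_max = 0.01) {
  assert_columns(calls, c("gene_id", "sample_id", "state"), "call matrix")
  samples <- unique(calls$sample_id)
  n_samples <- length(samples)
  if (n_samples < 10) abort("recurrence testing needs at least 10 samples")
  n_genes <- length(unique(calls$gene_id))
  out <- purrr::map(c(amp = "amp", del = "homdel"), function(st) {
    background <- mean(calls$state == st)
    if (background == 0) background <- 1 / (2 * n_samples * n_genes)
    calls |>
      group_by(.data$gene_id) |>
      summarise(n_altered = sum(.data$state == st),
                n_samples = dplyr::n(), .groups = "drop") |>
      mutate(frequency = .data$n_altered / .data$n_samples,
             background = background,
             p = pbinom(.data$n_altered - 1, .data$n_samples, background,
                        lower.tail = FALSE),
             q = bh_adjust(.data$p))
  })
  bind_rows(out, .id = "state") |>
    filter(.data$q < q_max, .data$frequency > .data$background,
           .data$n_altered > 0) |>
    select("gene_id", "state", "n_altered", "n_samples", "frequency",
           "background", "p", "q") |>
    arrange(.data$state, .data$q, .data$gene_id)
}
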