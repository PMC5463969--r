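#' File readers and writers for the pipeline's plain-text interchange formats
#'
#' All tabular interchange is tab-separated text. An omics matrix is stored
#' with the feature identifier in the first column (`feature_id`) and one
#' numeric column per sample; sample metadata is a three-column table
#' (`sample_id`, `patient_id`, `tissue`) with tissue in `{tumor, normal}`.
#' SEG files are 1-based inclusive; gene tables are BED-like, 0-based
#' half-open.
#'
#' @param path Path to the file.
#' @return A tibble (`read_truth()` returns a named list).
#' @name omix-io
NULL

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Validate a wide omics matrix
#'
#' Checks the tibble contract used throughout the package: a `feature_id`
#' character column followed by numeric sample columns, no duplicated
#' feature or sample identifiers.
#'
#' @param x A data frame with `feature_id` plus one numeric column per sample.
#' @param what Label used in error messages.
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_omics_matrix <- function(x, what = "omics matrix") {
  x <- as_tibble(x)
  assert_columns(x, "feature_id", what)
  if (anyDuplicated(x$feature_id)) abort(sprintf("%s has duplicate feature ids", what))
  samples <- setdiff(names(x), "feature_id")
  if (length(samples) == 0) abort(sprintf("%s has no sample columns", what))
  if (anyDuplicated(samples)) abort(sprintf("%s has duplicate sample ids", what))
  bad <- samples[!vapply(x[samples], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("%s has non-numeric sample column(s): %s",
                  what, paste(bad, collapse = ", ")))
  }
  x
}

#' Validate sample metadata
#'
#' @param meta Data frame with columns `sample_id`, `patient_id`, `tissue`.
#' @return `meta` as a tibble.
#' @export
validate_sample_meta <- function(meta) {
  meta <- as_tibble(meta)
  assert_columns(meta, c("sample_id", "patient_id", "tissue"), "sample metadata")
  if (anyDuplicated(meta$sample_id)) abort("sample metadata has duplicate sample ids")
  bad <- setdiff(unique(meta$tissue), c("tumor", "normal"))
  if (length(bad) > 0) {
    abort(sprintf("tissue must be 'tumor' or 'normal'; found: %s",
                  paste(bad, collapse = ", ")))
  }
  meta
}

# wide tibble -> numeric matrix with feature rownames
omx_as_matrix <- function(x) {
  x <- validate_omics_matrix(x)
  m <- as.matrix(x[setdiff(names(x), "feature_id")])
  rownames(m) <- x$feature_id
  m
}

omx_from_matrix <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(feature_id = rownames(m)), out)
}

#' @rdname omix-io
#' @export
read_omics_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "feature_id"
  validate_omics_matrix(x, basename(path))
}

#' @rdname omix-io
#' @param x,meta,segments,genes,targets,edges,truth Object to write.
#' @export
write_omics_matrix <- function(x, path) {
  readr::write_tsv(validate_omics_matrix(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname omix-io
#' @export
read_sample_meta <- function(path) {
  validate_sample_meta(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname omix-io
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(validate_sample_meta(meta), path, progress = FALSE)
  invisible(path)
}

#' @rdname omix-io
#' @export
read_seg <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(seg)[1:5] <- c("sample_id", "chromosome", "start", "end", "seg_mean")
  validate_seg(seg)
}

#' Validate a segment table (1-based inclusive coordinates)
#'
#' @param seg Data frame with columns `sample_id`, `chromosome`, `start`,
#'   `end`, `seg_mean`.
#' @return `seg` as a tibble.
#' @export
validate_seg <- function(seg) {
  seg <- as_tibble(seg)
  assert_columns(seg, c("sample_id", "chromosome", "start", "end", "seg_mean"),
                 "segment table")
  if (any(seg$start > seg$end)) abort("segment table has start > end")
  # per sample+chromosome, segments must not overlap (1-based inclusive)
  ovl <- seg |>
    arrange(.data$sample_id, .data$chromosome, .data$start) |>
    group_by(.data$sample_id, .data$chromosome) |>
    summarise(bad = any(.data$start[-1] <= .data$end[-length(.data$end)]),
              .groups = "drop")
  if (any(ovl$bad)) abort("segment table has overlapping segments within a sample")
  seg
}

#' @rdname omix-io
#' @export
write_seg <- function(segments, path) {
  readr::write_tsv(validate_seg(segments), path, progress = FALSE)
  invisible(path)
}

#' @rdname omix-io
#' @export
read_gene_table <- function(path) {
  g <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id"),
                       show_col_types = FALSE, progress = FALSE, comment = "#")
  if (any(g$start >= g$end)) abort("gene table has start >= end (0-based half-open expected)")
  if (anyDuplicated(g$gene_id)) abort("gene table has duplicate gene ids")
  g
}

#' @rdname omix-io
#' @export
write_gene_table <- function(genes, path) {
  assert_columns(genes, c("chrom", "start", "end", "gene_id"), "gene table")
  readr::write_tsv(genes[, c("chrom", "start", "end", "gene_id")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname omix-io
#' @export
read_target_map <- function(path) {
  t <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(t, c("mirna_id", "gene_id", "n_algorithms"), "target map")
  validate_target_map(t)
}

#' Validate a miRNA-to-gene target map
#'
#' @param targets Data frame with columns `mirna_id`, `gene_id`,
#'   `n_algorithms` (prediction-algorithm support count, at least 1).
#' @return `targets` as a tibble.
#' @export
validate_target_map <- function(targets) {
  targets <- as_tibble(targets)
  assert_columns(targets, c("mirna_id", "gene_id", "n_algorithms"), "target map")
  if (any(targets$n_algorithms < 1)) abort("n_algorithms must be >= 1")
  if (anyDuplicated(targets[, c("mirna_id", "gene_id")])) {
    abort("target map has duplicate (mirna_id, gene_id) pairs")
  }
  targets
}

#' @rdname omix-io
#' @export
write_target_map <- function(targets, path) {
  readr::write_tsv(validate_target_map(targets), path, progress = FALSE)
  invisible(path)
}

#' @rdname omix-io
#' @export
read_ppi_edges <- function(path) {
  e <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(e, c("gene_a", "gene_b", "score"), "edge list")
  if (any(e$score < 0 | e$score > 1)) abort("edge scores must lie in [0, 1]")
  as_tibble(e)
}

#' @rdname omix-io
#' @export
write_ppi_edges <- function(edges, path) {
  assert_columns(edges, c("gene_a", "gene_b", "score"), "edge list")
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname omix-io
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("de_genes_up", "de_genes_down", "de_mirnas_up", "de_mirnas_down",
              "triple_gene")) {
    truth[[f]] <- as.character(unlist(truth[[f]]))
  }
  for (f in c("planted_pairs", "planted_meth", "planted_cna", "key_genes")) {
    truth[[f]] <- as_tibble(truth[[f]])
  }
  truth
}

#' @rdname omix-io
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname omix-io
#' @export
read_site_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(m, c("site_id", "gene_id"), "site-to-gene map")
  as_tibble(m)
}

#' @rdname omix-io
#' @export
write_site_map <- function(x, path) {
  assert_columns(x, c("site_id", "gene_id"), "site-to-gene map")
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
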