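#' Assemble a full pipeline configuration
#'
#' Collects every stage threshold in one validated object, together with
#' either a simulation block ([cohort_config()]) or a directory of input
#' files in the layout written by [write_cohort_fixtures()].
#'
#' @param simulate A [cohort_config()] describing the cohort to simulate,
#'   or `NULL` when reading files from `input_dir`.
#' @param input_dir Directory of input files (used when `simulate` is
#'   `NULL`).
#' @param gene_sets Gene-set tibble ([read_gmt()]) or path to a GMT file;
#'   `NULL` simulates annotation sets for simulated cohorts and skips
#'   enrichment otherwise.
#' @param fc_min,p_max DEG thresholds: fold change at least `fc_min` and
#'   BH-adjusted p strictly below `p_max`.
#' @param min_algorithms Minimum miRNA target-prediction support.
#' @param r_max,pair_p_max Functional miRNA-gene pair gates (`r < r_max`,
#'   `p < pair_p_max`).
#' @param cna_r_min,cna_p_max Expression-dosage gates for CNA candidates.
#' @param score_min Minimum PPI interaction score.
#' @param hub_k Top-k rank cutoff for hub calling.
#' @param enrich_p_max Adjusted-p threshold for enrichment.
#' @param call_thresholds [cna_thresholds()] for five-state calling.
#' @param recurrence_q_max q threshold for recurrent CNA genes.
#' @param seed Overrides the simulation seed when given.
#' @return A validated `run_config` list.
#' @export
run_config <- function(simulate = cohort_config(), input_dir = NULL,
                       gene_sets = NULL, fc_min = 2, p_max = 0.01,
                       min_algorithms = 3, r_max = -0.1, pair_p_max = 0.05,
                       cna_r_min = 0.5, cna_p_max = 0.05, score_min = 0.4,
                       hub_k = 10, enrich_p_max = 0.05,
                       call_thresholds = cna_thresholds(),
                       recurrence_q_max = 0.01, seed = NULL) {
  if (is.null(simulate) && is.null(input_dir)) {
    abort("either a simulate block or an input_dir is required")
  }
  if (!is.null(simulate)) {
    if (!inherits(simulate, "cohort_config")) simulate <- do.call(cohort_config, simulate)
    if (!is.null(seed)) simulate$seed <- as.integer(seed)
  }
  for (nm in c("p_max", "pair_p_max", "cna_p_max", "enrich_p_max",
               "recurrence_q_max")) {
    v <- get(nm)
    if (v <= 0 || v > 1) abort(sprintf("%s must lie in (0, 1]", nm))
  }
  if (fc_min < 1) abort("fc_min must be >= 1")
  if (score_min < 0 || score_min > 1) abort("score_min must lie in [0, 1]")
  if (hub_k < 1) abort("hub_k must be a positive count")
  if (min_algorithms < 1) abort("min_algorithms must be a positive count")
  call_thresholds <- do.call(cna_thresholds, call_thresholds)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  structure(list(simulate = simulate, input_dir = input_dir,
                 gene_sets = gene_sets, fc_min = fc_min, p_max = p_max,
                 min_algorithms = min_algorithms, r_max = r_max,
                 pair_p_max = pair_p_max, cna_r_min = cna_r_min,
                 cna_p_max = cna_p_max, score_min = score_min, hub_k = hub_k,
                 enrich_p_max = enrich_p_max, call_thresholds = call_thresholds,
                 recurrence_q_max = recurrence_q_max, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulate`
#' mapping is passed to [cohort_config()] and `call_thresholds` to
#' [cna_thresholds()]. `overrides` (named list) wins over file values, so a
#' caller can override any key without editing the file.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list of values overriding the file's keys.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$simulate)) raw$simulate <- do.call(cohort_config, raw$simulate)
  do.call(run_config, raw)
}

empty_centrality <- function() {
  structure(tibble(gene_id = character(0), degree = integer(0),
                   betweenness = double(0), closeness = double(0),
                   degree_rank = integer(0), betweenness_rank = integer(0),
                   closeness_rank = integer(0)),
            class = c("omx_centrality", "tbl_df", "tbl", "data.frame"))
}

stage_msg <- function(stage, fmt, ...) {
  inform(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full multi-omics integration pipeline
#'
#' Executes the stages in dependency order: simulate (or load) the cohort;
#' paired differential analysis of genes, miRNAs and gene-level
#' methylation; copy-number mapping, five-state calling and recurrence;
#' bimodal filtering into the three candidate sets with correlation gates
#' and overlap analysis; DEG network construction, per-mechanism
#' seed-plus-neighbor subnetworks, centralities and hub calls (including
#' the cross-network degree rule); and gene-set enrichment of each
#' subnetwork. Every intermediate table is written to `out_dir` and
#' fingerprinted in a JSON manifest, so identical configs yield
#' hash-identical manifests.
#'
#' @param config A [run_config()] (a [cohort_config()] is also accepted and
#'   wrapped with default thresholds).
#' @param out_dir Output directory; defaults to a fresh temporary
#'   directory.
#' @param quiet Suppress per-stage progress messages.
#' @return An `omx_run` list: `cohort`, `differential` (list of the three
#'   classified tables), `cna` (`ratios`, `calls`, `recurrent`),
#'   `integration` (`pairs`, `functional_pairs`, `candidates`, `overlap`),
#'   `network` (`deg_graph`, `subnetworks`, `centralities`, `hubs`,
#'   `cross_network`, `key_genes`), `enrichment`, `summary`, `manifest`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  if (inherits(config, "cohort_config")) config <- run_config(simulate = config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% tempfile("omx_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- if (quiet) function(...) invisible() else stage_msg

  # --- stage: cohort -------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    gene_sets <- config$gene_sets %||% simulate_gene_sets(cohort)
    say("cohort", "simulated %d genes x %d samples (seed %d)",
        nrow(cohort$expression), nrow(cohort$sample_meta), config$simulate$seed)
  } else {
    cohort <- read_cohort_fixtures(config$input_dir)
    gene_sets <- config$gene_sets
    say("cohort", "loaded input files from %s", config$input_dir)
  }
  meta <- cohort$sample_meta
  tumor_samples <- meta$sample_id[meta$tissue == "tumor"]

  # --- stage: differential -------------------------------------------------
  gene_de <- classify_differential(
    paired_moderated_test(cohort$expression, meta),
    fc_min = config$fc_min, p_max = config$p_max)
  mirna_de <- classify_differential(
    paired_moderated_test(cohort$mirna, meta),
    fc_min = config$fc_min, p_max = config$p_max)
  meth_gene <- aggregate_probes_to_genes(cohort$methylation, cohort$site_map)
  meth_de <- classify_differential(
    paired_moderated_test(meth_gene, meta, log_transform = TRUE, pseudocount = 0),
    fc_min = config$fc_min, p_max = config$p_max)
  say("differential", "%d/%d DEGs up/down; %d DE miRNAs; %d differentially methylated genes",
      sum(gene_de$status == "up"), sum(gene_de$status == "down"),
      sum(mirna_de$status != "ns"), sum(meth_de$status != "ns"))

  # --- stage: copy number --------------------------------------------------
  ratios <- map_segments_to_genes(cohort$segments, cohort$genes)
  calls <- call_cna_states(ratios, config$call_thresholds)
  recurrent <- recurrent_cna_genes(calls, q_max = config$recurrence_q_max)
  say("cna", "%d recurrently altered genes (%d amp, %d del)",
      nrow(recurrent), sum(recurrent$state == "amp"), sum(recurrent$state == "del"))

  # --- stage: integration --------------------------------------------------
  targets <- filter_targets(cohort$targets, config$min_algorithms)
  mb <- mirna_bimodal_filter(gene_de, mirna_de, targets)
  pair_cor <- correlate_features(
    dplyr::rename(mb$pairs[, c("mirna_id", "gene_id")],
                  id_a = "mirna_id", id_b = "gene_id"),
    cohort$mirna, cohort$expression, samples = tumor_samples)
  fpairs <- functional_pairs(pair_cor, r_max = config$r_max,
                             p_max = config$pair_p_max)
  meth_set <- methylation_bimodal_filter(gene_de, meth_de)
  cna_set <- cna_bimodal_filter(gene_de, recurrent, cohort$expression, ratios,
                                r_min = config$cna_r_min,
                                p_max = config$cna_p_max)
  candidates <- candidate_gene_sets(mb$genes, meth_set, cna_set)
  overlap <- overlap_analysis(candidates)
  say("integration", "candidate sets: %d miRNA, %d methylation, %d CNA; %d in >=2 sets; %d in all three",
      nrow(mb$genes), nrow(meth_set), nrow(cna_set),
      length(overlap$in_two_or_more), length(overlap$triple))

  # --- stage: network ------------------------------------------------------
  degs <- gene_de$feature_id[gene_de$status != "ns"]
  deg_graph <- build_deg_network(cohort$ppi_edges, degs, config$score_min)
  seeds <- list(mirna = mb$genes$gene_id, methylation = meth_set$gene_id,
                cna = cna_set$gene_id)
  subnetworks <- purrr::map(seeds, function(s) {
    withCallingHandlers(extract_subnetwork(deg_graph, s),
                        warning = function(w) invokeRestart("muffleWarning"))
  })
  cents <- purrr::map(subnetworks, function(g) {
    if (igraph::vcount(g) == 0) empty_centrality() else centralities(g)
  })
  hubs <- purrr::imap(cents, function(ct, m) hub_call(ct, seeds[[m]], config$hub_k))
  hub_tbl <- bind_rows(hubs, .id = "network")
  cross <- cross_network_degree_rule(cents, unique(unlist(seeds)),
                                     k = config$hub_k,
                                     exclude = unique(hub_tbl$gene_id))
  key_genes <- union(unique(hub_tbl$gene_id), cross$gene_id)
  say("network", "subnetworks of %s nodes; %d hub calls + %d by the cross-network degree rule",
      paste(purrr::map_int(subnetworks, igraph::vcount), collapse = "/"),
      dplyr::n_distinct(hub_tbl$gene_id), nrow(cross))

  # --- stage: enrichment ---------------------------------------------------
  background <- cohort$expression$feature_id
  enrichment <- list()
  if (!is.null(gene_sets)) {
    enrichment <- purrr::imap(subnetworks, function(g, m) {
      q <- intersect(igraph::V(g)$name, background)
      if (length(q) == 0) {
        return(tibble(term_id = character(0), term_name = character(0),
                      overlap = integer(0), term_size = integer(0),
                      query_size = integer(0), background_size = integer(0),
                      p = double(0), p_adj = double(0)))
      }
      enrich(q, background, gene_sets, p_max = config$enrich_p_max)
    })
    say("enrichment", "significant terms per network: %s",
        paste(purrr::map_int(enrichment, nrow), collapse = "/"))
  }

  # --- outputs and manifest ------------------------------------------------
  summary <- list(
    n_deg_up = sum(gene_de$status == "up"),
    n_deg_down = sum(gene_de$status == "down"),
    n_de_mirnas = sum(mirna_de$status != "ns"),
    n_meth_genes = sum(meth_de$status != "ns"),
    n_recurrent_amp = sum(recurrent$state == "amp"),
    n_recurrent_del = sum(recurrent$state == "del"),
    n_candidates_mirna = nrow(mb$genes),
    n_candidates_methylation = nrow(meth_set),
    n_candidates_cna = nrow(cna_set),
    n_functional_pairs = nrow(fpairs),
    venn_regions = setNames(as.list(overlap$regions$n), overlap$regions$region),
    in_two_or_more = overlap$in_two_or_more,
    triple = overlap$triple,
    subnetwork_nodes = purrr::map_int(subnetworks, igraph::vcount),
    subnetwork_edges = purrr::map_int(subnetworks, igraph::ecount),
    hubs = purrr::map(hubs, "gene_id"),
    cross_network_genes = cross$gene_id,
    key_genes = sort(key_genes),
    n_enriched_terms = purrr::map_int(enrichment, nrow))

  files <- list(
    gene_differential = list(gene_de, "gene_differential.tsv"),
    mirna_differential = list(mirna_de, "mirna_differential.tsv"),
    methylation_gene_differential = list(meth_de, "methylation_gene_differential.tsv"),
    cna_calls = list(calls, "cna_calls.tsv"),
    cna_recurrent = list(recurrent, "cna_recurrent.tsv"),
    candidate_sets = list(tidy(candidates), "candidate_sets.tsv"),
    functional_pairs = list(
      dplyr::rename(fpairs, mirna_id = "id_a", gene_id = "id_b"),
      "functional_pairs.tsv"),
    hubs = list(hub_tbl, "hubs.tsv"),
    cross_network = list(cross, "cross_network_key_genes.tsv"))
  for (m in names(subnetworks)) {
    tg <- tidy_graph_tables(subnetworks[[m]])
    files[[paste0("network_", m, "_edges")]] <-
      list(tg$edges, sprintf("network_%s_edges.tsv", m))
    files[[paste0("network_", m, "_nodes")]] <-
      list(as_tibble(unclass_omx(cents[[m]])), sprintf("network_%s_nodes.tsv", m))
  }
  for (m in names(enrichment)) {
    files[[paste0("enrichment_", m)]] <-
      list(enrichment[[m]], sprintf("enrichment_%s.tsv", m))
  }
  for (nm in names(files)) {
    readr::write_tsv(as_tibble(unclass_omx(files[[nm]][[1]])),
                     file.path(out_dir, files[[nm]][[2]]), progress = FALSE)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(purrr::map_chr(files, 2), "summary.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("omixhub")),
    thresholds = config[c("fc_min", "p_max", "min_algorithms", "r_max",
                          "pair_p_max", "cna_r_min", "cna_p_max", "score_min",
                          "hub_k", "enrich_p_max", "recurrence_q_max")],
    call_thresholds = config$call_thresholds,
    simulate = if (!is.null(config$simulate)) unclass(config$simulate),
    input_dir = config$input_dir,
    summary = summary,
    files = lapply(setNames(written, written), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(cohort = cohort,
                 differential = list(gene = gene_de, mirna = mirna_de,
                                     methylation = meth_de),
                 cna = list(ratios = ratios, calls = calls,
                            recurrent = recurrent),
                 integration = list(pairs = mb$pairs, pair_correlations = pair_cor,
                                    functional_pairs = fpairs,
                                    candidates = candidates, overlap = overlap),
                 network = list(deg_graph = deg_graph, subnetworks = subnetworks,
                                centralities = cents, hubs = hubs,
                                cross_network = cross, key_genes = sort(key_genes)),
                 enrichment = enrichment,
                 summary = summary, manifest = manifest, out_dir = out_dir),
            class = "omx_run")
}

#' @export
print.omx_run <- function(x, ...) {
  s <- x$summary
  cat("<omx_run>\n")
  cat(sprintf("  DEGs: %d up / %d down; DE miRNAs: %d; DM genes: %d\n",
              s$n_deg_up, s$n_deg_down, s$n_de_mirnas, s$n_meth_genes))
  cat(sprintf("  candidates (miRNA/meth/CNA): %d/%d/%d; functional pairs: %d\n",
              s$n_candidates_mirna, s$n_candidates_methylation,
              s$n_candidates_cna, s$n_functional_pairs))
  cat(sprintf("  subnetwork nodes: %s; key genes: %s\n",
              paste(s$subnetwork_nodes, collapse = "/"),
              paste(s$key_genes, collapse = ", ")))
  cat(sprintf("  outputs: %s\n", x$out_dir))
  invisible(x)
}

#' Summarize a pipeline run
#'
#' @param x An `omx_run` from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble of the run's headline counts.
#' @export
glance.omx_run <- function(x, ...) {
  s <- x$summary
  tibble(n_deg = s$n_deg_up + s$n_deg_down, n_de_mirnas = s$n_de_mirnas,
         n_meth_genes = s$n_meth_genes,
         n_recurrent_cna = s$n_recurrent_amp + s$n_recurrent_del,
         n_candidates = s$n_candidates_mirna + s$n_candidates_methylation +
           s$n_candidates_cna,
         n_functional_pairs = s$n_functional_pairs,
         n_key_genes = length(s$key_genes))
}
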