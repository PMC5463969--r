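#' Configuration for a simulated paired tumor/normal multi-omics cohort
#'
#' The simulator emulates the shape of a paired tumor/normal cancer cohort
#' profiled on four layers: gene expression (RPKM-like), miRNA expression
#' (RPM-like), CpG methylation beta values, and segmented DNA copy number —
#' together with a miRNA target map, a scored protein-protein interaction
#' (PPI) edge list, and ground-truth labels for every planted effect.
#'
#' Planted signal comes in four flavours:
#' * plain differentially expressed (DE) genes and miRNAs with a
#'   `effect_log2fc` log2 shift in tumors;
#' * miRNA-repressed genes: a DE gene coupled to a DE miRNA of opposite
#'   direction through a shared per-patient latent factor, so their tumor
#'   expression is anti-correlated;
#' * methylation-silenced (or de-silenced) genes: CpG sites shifted on the
#'   logit scale opposite in sign to the expression change;
#' * copy-number dosage genes: per-tumor segment means drawn in the
#'   amplification (or homozygous-deletion) range drive the gene's
#'   expression, so expression and copy number are positively correlated.
#'
#' When all three planted counts are at least 1 the first planted gene of
#' each layer is one shared down-regulated gene carrying all three
#' alterations (hypermethylated, deleted, targeted by an up-regulated
#' miRNA), so the downstream candidate-set triple intersection is non-empty
#' by construction. Designated key genes are additionally wired to at
#' least 15 DE neighbors in the PPI graph so that their centrality in the
#' relevant subnetwork is high by construction.
#'
#' @param n_patients Number of patients; every patient has a tumor sample.
#' @param n_paired Number of patients that also have a matched normal
#'   sample (`<= n_patients`).
#' @param n_genes,n_mirnas,n_meth_sites Feature-space sizes.
#' @param frac_de_genes Fraction of genes (and miRNAs) planted as DE.
#' @param planted_mirna_pairs Number of (miRNA, gene) repression pairs.
#' @param planted_meth_genes Number of methylation-driven genes.
#' @param planted_cna_genes Number of copy-number-driven genes.
#' @param effect_log2fc Planted tumor-vs-normal shift, log2 units (also
#'   used, on the logit scale, for methylation shifts).
#' @param noise_sd Per-sample Gaussian noise on the log2 / logit scale.
#' @param ppi_edge_prob Background Erdos-Renyi edge probability of the PPI
#'   graph.
#' @param n_key_genes Number of planted high-centrality key genes (cycled
#'   over the miRNA, methylation and CNA mechanisms).
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows
#'   from it through a locally scoped generator.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 60, n_paired = 30, n_genes = 2000,
                          n_mirnas = 300, n_meth_sites = 4000,
                          frac_de_genes = 0.1, planted_mirna_pairs = 20,
                          planted_meth_genes = 20, planted_cna_genes = 20,
                          effect_log2fc = 2, noise_sd = 0.3,
                          ppi_edge_prob = 0.08, n_key_genes = 3, seed = 1) {
  cfg <- list(n_patients = n_patients, n_paired = n_paired, n_genes = n_genes,
              n_mirnas = n_mirnas, n_meth_sites = n_meth_sites,
              frac_de_genes = frac_de_genes,
              planted_mirna_pairs = planted_mirna_pairs,
              planted_meth_genes = planted_meth_genes,
              planted_cna_genes = planted_cna_genes,
              effect_log2fc = effect_log2fc, noise_sd = noise_sd,
              ppi_edge_prob = ppi_edge_prob, n_key_genes = n_key_genes,
              seed = seed)
  for (f in c("n_patients", "n_paired", "n_genes", "n_mirnas", "n_meth_sites")) {
    if (cfg[[f]] < 1) abort(sprintf("%s must be a positive count", f))
  }
  for (f in c("planted_mirna_pairs", "planted_meth_genes", "planted_cna_genes",
              "n_key_genes")) {
    if (cfg[[f]] < 0) abort(sprintf("%s must be a non-negative count", f))
  }
  if (cfg$n_paired > cfg$n_patients) abort("n_paired must be <= n_patients")
  if (cfg$frac_de_genes < 0 || cfg$frac_de_genes > 1) {
    abort("frac_de_genes must lie in [0, 1]")
  }
  if (cfg$ppi_edge_prob < 0 || cfg$ppi_edge_prob > 1) {
    abort("ppi_edge_prob must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be non-negative")
  n_de <- round(cfg$frac_de_genes * cfg$n_genes)
  triple <- as.integer(cfg$planted_mirna_pairs >= 1 &&
                       cfg$planted_meth_genes >= 1 && cfg$planted_cna_genes >= 1)
  need <- cfg$planted_mirna_pairs + cfg$planted_meth_genes +
    cfg$planted_cna_genes - 2L * triple
  if (need > n_de) {
    abort(sprintf(
      "planted gene counts (%d distinct genes) exceed the DE pool (%d of %d genes)",
      need, n_de, cfg$n_genes))
  }
  if (cfg$planted_mirna_pairs > cfg$n_mirnas) {
    abort("planted_mirna_pairs exceeds n_mirnas")
  }
  structure(cfg, class = "cohort_config")
}

# block structure along each chromosome: planted copy-number genes sit in
# singleton segments; runs of up to 25 background genes share one segment.
seg_blocks <- function(genes, planted_ids) {
  genes <- arrange(genes, .data$chrom, .data$start)
  planted <- genes$gene_id %in% planted_ids
  out <- vector("list", length(unique(genes$chrom)))
  blk <- integer(nrow(genes))
  b <- 0L
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    run <- 0L
    b <- b + 1L
    for (j in i) {
      if (planted[j]) {
        b <- b + 1L
        blk[j] <- b
        b <- b + 1L
        run <- 0L
      } else {
        run <- run + 1L
        if (run > 25L) {
          b <- b + 1L
          run <- 1L
        }
        blk[j] <- b
      }
    }
  }
  genes |>
    mutate(block = blk, planted = planted) |>
    group_by(.data$chrom, .data$block) |>
    summarise(start = min(.data$start) + 1L,  # to 1-based inclusive
              end = max(.data$end),
              planted_gene = if (any(.data$planted)) .data$gene_id[.data$planted][1] else NA_character_,
              .groups = "drop")
}

#' Simulate a paired tumor/normal multi-omics cohort with planted signal
#'
#' @param config A [cohort_config()].
#' @return A list of class `omx_cohort` with elements `expression`, `mirna`,
#'   `methylation` (wide omics tibbles), `sample_meta`, `site_map`,
#'   `segments` (SEG-style tibble, tumor samples only), `genes` (BED-like
#'   0-based half-open gene table), `targets`, `ppi_edges`, `truth`
#'   (ground-truth labels) and `config`.
#' @seealso [write_cohort_fixtures()], [run_pipeline()]
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  cfg <- config
  with_local_seed(cfg$seed, {
    w <- max(4, nchar(as.character(cfg$n_genes)))
    gene_ids <- sprintf(paste0("G%0", w, "d"), seq_len(cfg$n_genes))
    mirna_ids <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))
    site_ids <- sprintf(paste0("S%0", w + 1, "d"), seq_len(cfg$n_meth_sites))
    patients <- sprintf("P%03d", seq_len(cfg$n_patients))
    tumor_ids <- paste0(patients, "-T")
    normal_ids <- paste0(patients[seq_len(cfg$n_paired)], "-N")
    sample_meta <- tibble(
      sample_id = c(tumor_ids, normal_ids),
      patient_id = c(patients, patients[seq_len(cfg$n_paired)]),
      tissue = c(rep("tumor", cfg$n_patients), rep("normal", cfg$n_paired)))
    samples <- sample_meta$sample_id
    n_s <- length(samples)
    is_tumor <- sample_meta$tissue == "tumor"

    # gene coordinates: contiguous runs per chromosome, 100 kb spacing,
    # 10 kb footprints, BED-style 0-based half-open
    per_chr <- ceiling(cfg$n_genes / 22)
    chr_idx <- (seq_len(cfg$n_genes) - 1L) %/% per_chr + 1L
    within <- (seq_len(cfg$n_genes) - 1L) %% per_chr
    genes <- tibble(chrom = paste0("chr", chr_idx),
                    start = (within + 1L) * 100000L,
                    end = (within + 1L) * 100000L + 10000L,
                    gene_id = gene_ids)

    # --- DE assignment -----------------------------------------------------
    n_de <- round(cfg$frac_de_genes * cfg$n_genes)
    de_ids <- sample(gene_ids, n_de)
    n_up <- ceiling(n_de / 2)
    up_ids <- de_ids[seq_len(n_up)]
    down_ids <- setdiff(de_ids, up_ids)
    delta <- setNames(numeric(cfg$n_genes), gene_ids)
    delta[up_ids] <- cfg$effect_log2fc
    delta[down_ids] <- -cfg$effect_log2fc

    # --- planted gene allocation ------------------------------------------
    # planted candidate genes are kept off the high-degree tail of the
    # power-law PPI background (node fitness grows with index in the static
    # fitness model), so subnetwork top-10 rankings are contested by
    # unplanted DEG hubs and the only planted genes with high centrality are
    # the star-wired key genes
    low_fitness <- gene_ids[seq_len(cfg$n_genes %/% 2)]
    down_low <- intersect(down_ids, low_fitness)
    plant_triple <- cfg$planted_mirna_pairs >= 1 && cfg$planted_meth_genes >= 1 &&
      cfg$planted_cna_genes >= 1 && length(down_low) >= 1
    triple_gene <- if (plant_triple) down_low[1] else character(0)
    pool <- setdiff(intersect(de_ids, low_fitness), triple_gene)
    need <- cfg$planted_mirna_pairs + cfg$planted_meth_genes +
      cfg$planted_cna_genes - 2L * as.integer(plant_triple)
    if (need > length(pool)) {
      abort(sprintf(
        "planted gene counts (%d distinct genes) exceed the plantable DE pool (%d genes)",
        need, length(pool)))
    }
    take <- function(k) {
      picked <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      picked
    }
    n_extra_mirna <- cfg$planted_mirna_pairs - as.integer(plant_triple)
    n_extra_meth <- cfg$planted_meth_genes - as.integer(plant_triple)
    n_extra_cna <- cfg$planted_cna_genes - as.integer(plant_triple)
    mirna_genes <- c(triple_gene, if (n_extra_mirna > 0) take(n_extra_mirna))
    meth_genes <- c(triple_gene, if (n_extra_meth > 0) take(n_extra_meth))
    cna_genes <- c(triple_gene, if (n_extra_cna > 0) take(n_extra_cna))

    # copy-number-driven genes express through dosage, not a fixed shift
    delta[cna_genes] <- 0

    # key genes are picked now so their planted effects can carry extra
    # margin; one per mechanism, cycling, never the shared triple-layer gene
    mech_pools <- list(mirna = setdiff(mirna_genes, triple_gene),
                       methylation = setdiff(meth_genes, triple_gene),
                       cna = setdiff(cna_genes, triple_gene))
    key <- tibble(gene_id = character(0), mechanism = character(0))
    if (cfg$n_key_genes > 0) {
      mech_cycle <- rep(names(mech_pools), length.out = cfg$n_key_genes)
      used <- character(0)
      for (m in mech_cycle) {
        cand <- setdiff(mech_pools[[m]], used)
        if (length(cand) == 0) next
        key <- bind_rows(key, tibble(gene_id = cand[1], mechanism = m))
        used <- c(used, cand[1])
      }
    }

    # --- copy-number dosage and segments ----------------------------------
    # plain planted genes: dosage spread wide enough for a population
    # expression-dosage correlation near 0.65; key and triple-layer genes
    # get a wider spread so their r > 0.5 gate holds with margin
    cna_state <- setNames(ifelse(cna_genes %in% up_ids, "amp", "del"), cna_genes)
    if (plant_triple) cna_state[triple_gene] <- "del"
    boosted <- c(triple_gene, key$gene_id[key$mechanism == "cna"])
    n_t <- cfg$n_patients
    dose <- matrix(0, nrow = length(cna_genes), ncol = n_t,
                   dimnames = list(cna_genes, tumor_ids))
    for (g in cna_genes) {
      wide <- g %in% boosted
      dose[g, ] <- switch(cna_state[[g]],
        amp = runif(n_t, 0.9, if (wide) 2.8 else 1.8),
        del = -runif(n_t, 1.3, if (wide) 3.2 else 2.2))
    }

    blocks <- seg_blocks(genes, cna_genes)
    n_blk <- nrow(blocks)
    segments <- tidyr::expand_grid(sample_id = tumor_ids, blocks) |>
      mutate(seg_mean = rnorm(n_blk * n_t, 0, 0.05))
    planted_rows <- which(!is.na(segments$planted_gene))
    segments$seg_mean[planted_rows] <-
      dose[cbind(segments$planted_gene[planted_rows],
                 segments$sample_id[planted_rows])]
    segments <- segments |>
      mutate(num_mark = pmax(10L, (.data$end - .data$start) %/% 5000L)) |>
      select("sample_id", chromosome = "chrom", "start", "end", "seg_mean",
             "num_mark") |>
      arrange(.data$sample_id, .data$chromosome, .data$start)

    # --- miRNA layer -------------------------------------------------------
    n_de_mir <- max(cfg$planted_mirna_pairs, round(cfg$frac_de_genes * cfg$n_mirnas))
    de_mirna_ids <- sample(mirna_ids, n_de_mir)
    pair_mirnas <- de_mirna_ids[seq_len(cfg$planted_mirna_pairs)]
    # planted miRNA direction is opposite to its target gene
    mir_delta <- setNames(numeric(cfg$n_mirnas), mirna_ids)
    pair_gene_dir <- ifelse(mirna_genes %in% up_ids & !(mirna_genes %in% triple_gene),
                            "up", "down")
    if (plant_triple) pair_gene_dir[mirna_genes == triple_gene] <- "down"
    mir_delta[pair_mirnas] <- ifelse(pair_gene_dir == "up", -1, 1) * cfg$effect_log2fc
    extra_mir <- setdiff(de_mirna_ids, pair_mirnas)
    if (length(extra_mir) > 0) {
      mir_delta[extra_mir] <- rep(c(1, -1), length.out = length(extra_mir)) *
        cfg$effect_log2fc
    }

    # --- expression matrices ----------------------------------------------
    mu_g <- setNames(runif(cfg$n_genes, 3, 8), gene_ids)
    log2_expr <- matrix(rnorm(cfg$n_genes * n_s, 0, cfg$noise_sd),
                        nrow = cfg$n_genes,
                        dimnames = list(gene_ids, samples)) + mu_g
    log2_expr[, is_tumor] <- log2_expr[, is_tumor] + delta
    if (length(cna_genes) > 0) {
      log2_expr[cna_genes, tumor_ids] <- log2_expr[cna_genes, tumor_ids] + dose
    }
    # shared per-patient latent factor couples each planted pair
    n_pairs <- cfg$planted_mirna_pairs
    if (n_pairs > 0) {
      u <- matrix(rnorm(n_pairs * n_t), nrow = n_pairs,
                  dimnames = list(NULL, tumor_ids))
      a <- ifelse(mirna_genes %in% triple_gene, 0.4, 0.5)
      log2_expr[mirna_genes, tumor_ids] <-
        log2_expr[mirna_genes, tumor_ids] + a * u
    }
    mu_m <- setNames(runif(cfg$n_mirnas, 3, 8), mirna_ids)
    log2_mir <- matrix(rnorm(cfg$n_mirnas * n_s, 0, cfg$noise_sd),
                       nrow = cfg$n_mirnas,
                       dimnames = list(mirna_ids, samples)) + mu_m
    log2_mir[, is_tumor] <- log2_mir[, is_tumor] + mir_delta
    if (n_pairs > 0) {
      log2_mir[pair_mirnas, tumor_ids] <- log2_mir[pair_mirnas, tumor_ids] - a * u
    }

    # --- methylation layer -------------------------------------------------
    meth_dir <- setNames(ifelse(meth_genes %in% up_ids &
                                  !(meth_genes %in% triple_gene),
                                "hypo", "hyper"), meth_genes)
    # planted genes get 2 CpG sites each; remaining sites spread round-robin
    site_gene <- character(cfg$n_meth_sites)
    k <- 0L
    for (g in meth_genes) {
      nsite <- min(2L, cfg$n_meth_sites - k)
      site_gene[k + seq_len(nsite)] <- g
      k <- k + nsite
    }
    rest <- setdiff(gene_ids, meth_genes)
    if (k < cfg$n_meth_sites) {
      site_gene[(k + 1):cfg$n_meth_sites] <-
        rep(rest, length.out = cfg$n_meth_sites - k)
    }
    site_map <- tibble(site_id = site_ids, gene_id = site_gene)
    base_beta <- runif(cfg$n_meth_sites, 0.2, 0.8)
    hyper_sites <- site_gene %in% meth_genes[meth_dir == "hyper"]
    hypo_sites <- site_gene %in% meth_genes[meth_dir == "hypo"]
    base_beta[hyper_sites] <- runif(sum(hyper_sites), 0.15, 0.30)
    base_beta[hypo_sites] <- runif(sum(hypo_sites), 0.45, 0.70)
    shift <- numeric(cfg$n_meth_sites)
    shift[hyper_sites] <- cfg$effect_log2fc
    shift[hypo_sites] <- -cfg$effect_log2fc
    z <- matrix(rnorm(cfg$n_meth_sites * n_s, 0, cfg$noise_sd),
                nrow = cfg$n_meth_sites,
                dimnames = list(site_ids, samples)) + qlogis(base_beta)
    z[, is_tumor] <- z[, is_tumor] + shift
    beta <- plogis(z)

    # --- miRNA target map --------------------------------------------------
    planted_pairs <- tibble(mirna_id = pair_mirnas, gene_id = mirna_genes,
                            mechanism = rep("repression", n_pairs))
    n_decoy <- max(100L, 5L * n_pairs)
    decoys <- tibble(mirna_id = sample(mirna_ids, 4 * n_decoy, replace = TRUE),
                     gene_id = sample(gene_ids, 4 * n_decoy, replace = TRUE)) |>
      distinct() |>
      anti_join(planted_pairs, by = c("mirna_id", "gene_id")) |>
      head(n_decoy) |>
      mutate(n_algorithms = sample(1:5, n(), replace = TRUE))
    targets <- bind_rows(
      planted_pairs |>
        select("mirna_id", "gene_id") |>
        mutate(n_algorithms = sample(3:5, n_pairs, replace = TRUE)),
      decoys) |>
      arrange(.data$mirna_id, .data$gene_id)

    # --- PPI graph ---------------------------------------------------------
    # heavy-tailed background degrees, as in real PPI networks: the graph's
    # high-degree nodes give "top 10" rankings something to be selective
    # against, so subnetwork centrality is informative rather than tied
    n_bg_edges <- round(cfg$ppi_edge_prob * cfg$n_genes * (cfg$n_genes - 1) / 2)
    bg_graph <- igraph::sample_fitness_pl(cfg$n_genes, n_bg_edges,
                                          exponent.out = 2.3)
    bg <- igraph::as_edgelist(bg_graph, names = FALSE)
    bg_edges <- tibble(gene_a = gene_ids[pmin(bg[, 1], bg[, 2])],
                       gene_b = gene_ids[pmax(bg[, 1], bg[, 2])],
                       score = runif(nrow(bg), 0.15, 1))
    # star attachments: each key gene is wired to 30 DE genes that carry no
    # planted regulatory alteration, so subnetwork leaves are not candidates
    # and the key gene outranks the background's high-degree nodes
    planted_all <- unique(c(mirna_genes, meth_genes, cna_genes))
    null_de <- setdiff(de_ids, c(planted_all, key$gene_id))
    star_edges <- NULL
    if (nrow(key) > 0 && length(null_de) > 0) {
      leaves_per_key <- min(30L, length(null_de) %/% nrow(key))
      if (leaves_per_key < 15) {
        warn(sprintf(
          "only %d unplanted DE genes available per key gene (< 15); key-gene centrality is not guaranteed",
          leaves_per_key))
      }
      leaf_pool <- sample(null_de)
      star_edges <- purrr::map2_dfr(key$gene_id, seq_len(nrow(key)), function(g, i) {
        leaves <- leaf_pool[(i - 1) * leaves_per_key + seq_len(leaves_per_key)]
        tibble(gene_a = pmin(g, leaves), gene_b = pmax(g, leaves),
               score = runif(length(leaves), 0.6, 0.999))
      })
    }
    ppi_edges <- bind_rows(star_edges, bg_edges) |>
      distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
      arrange(.data$gene_a, .data$gene_b)

    truth <- list(
      de_genes_up = sort(up_ids), de_genes_down = sort(down_ids),
      de_mirnas_up = sort(names(mir_delta)[mir_delta > 0]),
      de_mirnas_down = sort(names(mir_delta)[mir_delta < 0]),
      planted_pairs = planted_pairs,
      planted_meth = tibble(gene_id = meth_genes,
                            direction = unname(meth_dir[meth_genes])),
      planted_cna = tibble(gene_id = cna_genes,
                           state = unname(cna_state[cna_genes])),
      key_genes = key,
      triple_gene = triple_gene)

    structure(list(
      expression = omx_from_matrix(round(2 ^ log2_expr, 6)),
      mirna = omx_from_matrix(round(2 ^ log2_mir, 6)),
      methylation = omx_from_matrix(round(beta, 6)),
      sample_meta = sample_meta,
      site_map = site_map,
      segments = segments,
      genes = genes,
      targets = targets,
      ppi_edges = ppi_edges,
      truth = truth,
      config = cfg), class = "omx_cohort")
  })
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Emits the cohort as the interchange formats the readers in this package
#' consume (TSV matrices, sample metadata, SEG, BED-like gene table,
#' target map, PPI edge list, site map, truth JSON), so a simulated cohort
#' round-trips through the same file interface a real cohort would use.
#'
#' @param cohort An `omx_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return A manifest tibble with columns `name`, `file`, `md5`.
#' @export
write_cohort_fixtures <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "omx_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  files <- c(expression = "expression.tsv", mirna = "mirna.tsv",
             methylation = "methylation.tsv", sample_meta = "samples.tsv",
             site_map = "site_map.tsv", segments = "segments.seg",
             genes = "genes.bed", targets = "targets.tsv",
             ppi_edges = "ppi_edges.tsv", truth = "truth.json")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write_omics_matrix(cohort$expression, paths[["expression"]])
  write_omics_matrix(cohort$mirna, paths[["mirna"]])
  write_omics_matrix(cohort$methylation, paths[["methylation"]])
  write_sample_meta(cohort$sample_meta, paths[["sample_meta"]])
  write_site_map(cohort$site_map, paths[["site_map"]])
  write_seg(cohort$segments, paths[["segments"]])
  write_gene_table(cohort$genes, paths[["genes"]])
  write_target_map(cohort$targets, paths[["targets"]])
  write_ppi_edges(cohort$ppi_edges, paths[["ppi_edges"]])
  write_truth(cohort$truth, paths[["truth"]])
  tibble(name = names(files), file = unname(files),
         md5 = unname(tools::md5sum(paths)))
}

#' Read a cohort back from fixture files written by [write_cohort_fixtures()]
#'
#' @param dir Directory containing the fixture files.
#' @return An `omx_cohort` list (without a `config` element).
#' @export
read_cohort_fixtures <- function(dir) {
  structure(list(
    expression = read_omics_matrix(file.path(dir, "expression.tsv")),
    mirna = read_omics_matrix(file.path(dir, "mirna.tsv")),
    methylation = read_omics_matrix(file.path(dir, "methylation.tsv")),
    sample_meta = read_sample_meta(file.path(dir, "samples.tsv")),
    site_map = read_site_map(file.path(dir, "site_map.tsv")),
    segments = read_seg(file.path(dir, "segments.seg")),
    genes = read_gene_table(file.path(dir, "genes.bed")),
    targets = read_target_map(file.path(dir, "targets.tsv")),
    ppi_edges = read_ppi_edges(file.path(dir, "ppi_edges.tsv")),
    truth = read_truth(file.path(dir, "truth.json"))), class = "omx_cohort")
}

#' Simulate gene-set annotations for a cohort
#'
#' Builds a small gene-set collection over the cohort's gene universe:
#' random sets plus one "planted pathway" per regulatory mechanism made of
#' that mechanism's planted genes topped up with random members, so
#' over-representation of recovered candidates is detectable.
#'
#' @param cohort An `omx_cohort`.
#' @param n_sets Number of random background sets.
#' @param set_size Size range (inclusive) for random sets.
#' @param seed Seed for the set draw (defaults to the cohort seed + 1).
#' @return A gene-set collection tibble (`term_id`, `term_name`, `members`
#'   list-column) as returned by [read_gmt()].
#' @export
simulate_gene_sets <- function(cohort, n_sets = 40, set_size = c(10, 50),
                               seed = NULL) {
  stopifnot(inherits(cohort, "omx_cohort"))
  seed <- seed %||% (cohort$config$seed + 1L)
  universe <- cohort$expression$feature_id
  truth <- cohort$truth
  with_local_seed(seed, {
    random_sets <- purrr::map(seq_len(n_sets), function(i) {
      sort(sample(universe, sample(seq(set_size[1], set_size[2]), 1)))
    })
    planted <- list(
      PLANTED_MIRNA = truth$planted_pairs$gene_id,
      PLANTED_METH = truth$planted_meth$gene_id,
      PLANTED_CNA = truth$planted_cna$gene_id)
    planted <- planted[vapply(planted, length, integer(1)) > 0]
    planted <- purrr::map(planted, function(g) {
      sort(unique(c(g, sample(universe, 10))))
    })
    tibble(
      term_id = c(names(planted), sprintf("RS%03d", seq_len(n_sets))),
      term_name = c(sprintf("planted pathway: %s", names(planted)),
                    sprintf("random set %d", seq_len(n_sets))),
      members = c(planted, random_sets))
  })
}
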