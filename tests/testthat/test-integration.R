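de_row <- function(id, status) {
  tibble::tibble(feature_id = id, log2fc = ifelse(status == "up", 2,
                                                  ifelse(status == "down", -2, 0)),
                 t = 0, p_raw = 0.001, p_adj = ifelse(status == "ns", 0.5, 0.001),
                 status = status)
}

test_that("target-support filtering keeps pairs with at least 3 algorithms", {
  tm <- tibble::tibble(mirna_id = c("m1", "m2", "m3"),
                       gene_id = c("g1", "g2", "g3"),
                       n_algorithms = c(3, 2, 5))
  out <- filter_targets(tm)
  expect_setequal(out$mirna_id, c("m1", "m3"))
  withr::local_seed(2)
  rnd <- tibble::tibble(mirna_id = sprintf("m%03d", 1:200),
                        gene_id = sprintf("g%03d", 1:200),
                        n_algorithms = sample(1:5, 200, replace = TRUE))
  expect_equal(filter_targets(rnd, 4), rnd[rnd$n_algorithms >= 4, ])
})

test_that("the miRNA filter keeps only discordant DE pairs", {
  gene_de <- dplyr::bind_rows(de_row("gUp", "up"), de_row("gDown", "down"),
                              de_row("gNs", "ns"))
  mirna_de <- dplyr::bind_rows(de_row("mUp", "up"), de_row("mDown", "down"),
                               de_row("mNs", "ns"))
  tm <- tidyr::expand_grid(mirna_id = c("mUp", "mDown", "mNs"),
                           gene_id = c("gUp", "gDown", "gNs")) |>
    dplyr::mutate(n_algorithms = 5)
  out <- mirna_bimodal_filter(gene_de, mirna_de, tm)
  expect_equal(nrow(out$pairs), 2)
  expect_setequal(paste(out$pairs$mirna_id, out$pairs$gene_id),
                  c("mUp gDown", "mDown gUp"))
  expect_setequal(out$genes$gene_id, c("gDown", "gUp"))
  expect_equal(out$genes$direction[out$genes$gene_id == "gDown"], "down")
})

test_that("a gene kept by several miRNAs is listed once with all of them", {
  gene_de <- de_row("gDown", "down")
  mirna_de <- dplyr::bind_rows(de_row("mA", "up"), de_row("mB", "up"))
  tm <- tibble::tibble(mirna_id = c("mA", "mB"), gene_id = "gDown",
                       n_algorithms = 4)
  out <- mirna_bimodal_filter(gene_de, mirna_de, tm)
  expect_equal(nrow(out$genes), 1)
  expect_equal(out$genes$n_mirnas, 2L)
  expect_equal(out$genes$mirnas, "mA,mB")
})

test_that("pairwise correlation matches the direct formula", {
  ma <- toy_matrix(matrix(c(1, 2, 3), nrow = 1,
                          dimnames = list("a", c("s1", "s2", "s3"))))
  mb <- toy_matrix(matrix(c(2, 4, 6, 6, 4, 2), nrow = 2, byrow = TRUE,
                          dimnames = list(c("b1", "b2"), c("s1", "s2", "s3"))))
  out <- correlate_features(tibble::tibble(id_a = c("a", "a"),
                                           id_b = c("b1", "b2")), ma, mb)
  expect_equal(out$r, c(1, -1))
  expect_equal(out$p, c(0, 0))

  withr::local_seed(5)
  n <- 20
  x <- rnorm(n)
  y <- rnorm(n)
  mx <- toy_matrix(matrix(x, 1, dimnames = list("x", sprintf("s%02d", 1:n))))
  my <- toy_matrix(matrix(y, 1, dimnames = list("y", sprintf("s%02d", 1:n))))
  got <- correlate_features(tibble::tibble(id_a = "x", id_b = "y"), mx, my)
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_ref <- r_ref * sqrt((n - 2) / (1 - r_ref^2))
  expect_equal(got$r, r_ref, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_ref), n - 2), tolerance = 1e-12)
  expect_equal(got$n, n)
})

test_that("zero-variance vectors yield undefined correlations, not errors", {
  mx <- toy_matrix(matrix(c(1, 1, 1, 1), 1,
                          dimnames = list("flat", sprintf("s%d", 1:4))))
  my <- toy_matrix(matrix(rnorm(4), 1,
                          dimnames = list("y", sprintf("s%d", 1:4))))
  expect_message(out <- correlate_features(
    tibble::tibble(id_a = "flat", id_b = "y"), mx, my), "undefined")
  expect_true(is.na(out$r))
  expect_equal(nrow(functional_pairs(out)), 0)
})

test_that("functional-pair gates are strict on both r and p", {
  rec <- tibble::tibble(id_a = "m", id_b = "g",
                        r = c(-0.05, -0.5, -0.5, -0.1),
                        p = c(0.01, 0.001, 0.2, 0.01), n = 30)
  out <- functional_pairs(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$r, -0.5)
  expect_equal(out$p, 0.001)
})

test_that("the methylation filter requires opposite directions", {
  gene_de <- dplyr::bind_rows(de_row("g1", "up"), de_row("g2", "up"),
                              de_row("g3", "ns"), de_row("g4", "down"))
  meth_de <- dplyr::bind_rows(de_row("g1", "down"), de_row("g2", "up"),
                              de_row("g3", "down"), de_row("g4", "up"))
  out <- methylation_bimodal_filter(gene_de, meth_de)
  expect_setequal(out$gene_id, c("g1", "g4"))
  expect_equal(out$methylation[out$gene_id == "g1"], "hypo")
  expect_equal(out$methylation[out$gene_id == "g4"], "hyper")
})

test_that("the CNA filter requires concordance plus a correlation gate", {
  gene_de <- dplyr::bind_rows(de_row("gAmpOk", "up"), de_row("gWrongDir", "up"),
                              de_row("gWeakCor", "down"))
  recurrent <- tibble::tibble(gene_id = c("gAmpOk", "gWrongDir", "gWeakCor"),
                              state = c("amp", "del", "del"))
  samples <- sprintf("s%02d", 1:20)
  withr::local_seed(6)
  dosage_ok <- runif(20, 0.9, 1.8)
  expr <- toy_matrix(rbind(
    gAmpOk = 2 ^ (6 + dosage_ok + rnorm(20, 0, 0.1)),
    gWrongDir = 2 ^ (6 + dosage_ok + rnorm(20, 0, 0.1)),
    gWeakCor = 2 ^ (6 + rnorm(20, 0, 1))) |>
      `colnames<-`(samples))
  ratios <- tibble::tibble(
    gene_id = rep(c("gAmpOk", "gWrongDir", "gWeakCor"), each = 20),
    sample_id = rep(samples, 3),
    log2_ratio = c(dosage_ok, dosage_ok, -runif(20, 1.3, 2.2)))
  out <- cna_bimodal_filter(gene_de, recurrent, expr, ratios)
  expect_equal(out$gene_id, "gAmpOk")   # concordant and strongly correlated
  expect_gt(out$r, 0.5)
  # the discordant gene is excluded no matter how well it correlates
  expect_false("gWrongDir" %in% out$gene_id)
  expect_false("gWeakCor" %in% out$gene_id)
})

test_that("overlap analysis enumerates the seven Venn regions", {
  sets <- candidate_gene_sets(
    tibble::tibble(gene_id = c("g1", "g2")),
    tibble::tibble(gene_id = c("g2", "g3")),
    tibble::tibble(gene_id = "g2"))
  ov <- overlap_analysis(sets)
  expect_equal(ov$triple, "g2")
  expect_equal(ov$in_two_or_more, "g2")
  counts <- setNames(ov$regions$n, ov$regions$region)
  expect_equal(unname(counts[c("mirna_only", "methylation_only", "all_three")]),
               c(1, 1, 1))

  disjoint <- candidate_gene_sets(
    tibble::tibble(gene_id = "a"), tibble::tibble(gene_id = "b"),
    tibble::tibble(gene_id = "c"))
  ovd <- overlap_analysis(disjoint)
  expect_length(ovd$in_two_or_more, 0)
  expect_length(ovd$triple, 0)
})

test_that("overlap region counts match brute-force membership enumeration", {
  withr::local_seed(9)
  universe <- sprintf("g%03d", 1:120)
  a <- sample(universe, 50)
  b <- sample(universe, 50)
  c_ <- sample(universe, 50)
  ov <- overlap_analysis(candidate_gene_sets(
    tibble::tibble(gene_id = a), tibble::tibble(gene_id = b),
    tibble::tibble(gene_id = c_)))
  counts <- setNames(ov$regions$n, ov$regions$region)
  ref <- sapply(universe, function(g) {
    paste0(ifelse(g %in% a, "A", ""), ifelse(g %in% b, "B", ""),
           ifelse(g %in% c_, "C", ""))
  })
  expect_equal(unname(counts["all_three"]), sum(ref == "ABC"))
  expect_equal(unname(counts["mirna_only"]), sum(ref == "A"))
  expect_equal(unname(counts["mirna_cna"]), sum(ref == "AC"))
  expect_equal(unname(counts["methylation_cna"]), sum(ref == "BC"))
  expect_setequal(ov$triple, universe[ref == "ABC"])
  expect_setequal(ov$in_two_or_more, universe[nchar(ref) >= 2])
})

test_that("relaxing the correlation gates never shrinks the functional set", {
  withr::local_seed(12)
  rec <- tibble::tibble(id_a = sprintf("m%02d", 1:50),
                        id_b = sprintf("g%02d", 1:50),
                        r = runif(50, -1, 1), p = runif(50), n = 30)
  strict <- functional_pairs(rec, r_max = -0.3, p_max = 0.01)
  loose <- functional_pairs(rec, r_max = -0.1, p_max = 0.05)
  expect_true(all(paste(strict$id_a, strict$id_b) %in%
                    paste(loose$id_a, loose$id_b)))
})

test_that("candidate sets are DEGs and obey their own admission rules", {
  run <- suppressMessages(run_pipeline(run_config(simulate = small_config(seed = 17)),
                                       quiet = TRUE))
  gene_de <- run$differential$gene
  degs <- gene_de$feature_id[gene_de$status != "ns"]
  cand <- run$integration$candidates
  all_cand <- unique(c(cand$mirna$gene_id, cand$methylation$gene_id,
                       cand$cna$gene_id))
  expect_true(all(all_cand %in% degs))
  # replay the direction rules on the outputs
  status <- setNames(gene_de$status, gene_de$feature_id)
  meth_status <- setNames(run$differential$methylation$status,
                          run$differential$methylation$feature_id)
  for (i in seq_len(nrow(cand$methylation))) {
    g <- cand$methylation$gene_id[i]
    expect_true((status[g] == "up" && meth_status[g] == "down") ||
                  (status[g] == "down" && meth_status[g] == "up"))
  }
  mirna_status <- setNames(run$differential$mirna$status,
                           run$differential$mirna$feature_id)
  for (i in seq_len(nrow(run$integration$pairs))) {
    pr <- run$integration$pairs[i, ]
    expect_true((mirna_status[pr$mirna_id] == "up" && status[pr$gene_id] == "down") ||
                  (mirna_status[pr$mirna_id] == "down" && status[pr$gene_id] == "up"))
  }
  expect_true(all(cand$cna$r > 0.5 & cand$cna$p < 0.05))
})
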