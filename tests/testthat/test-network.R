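test_that("DEG network construction applies score and membership rules", {
  edges <- tibble::tibble(
    gene_a = c("a", "a", "b", "c", "d", "e"),
    gene_b = c("b", "c", "c", "d", "d", "f"),
    score = c(0.4, 0.39, 0.9, 0.9, 0.5, 0.95))
  degs <- c("a", "b", "c", "d", "e")
  expect_message(g <- build_deg_network(edges, degs), "self-loop")
  # a-b at exactly 0.4 is kept; a-c fails the score gate; e-f has a non-DEG
  # endpoint; d-d is a self-loop; isolated DEG e is excluded
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(g), 3)
  expect_false(igraph::are_adjacent(g, "a", "c"))
  expect_true(igraph::are_adjacent(g, "a", "b"))
})

test_that("network construction equals brute-force filtering on random input", {
  withr::local_seed(33)
  ids <- sprintf("g%02d", 1:40)
  edges <- tibble::tibble(gene_a = sample(ids, 150, replace = TRUE),
                          gene_b = sample(ids, 150, replace = TRUE),
                          score = runif(150))
  degs <- sample(ids, 25)
  g <- suppressMessages(build_deg_network(edges, degs, 0.4))
  ref <- edges[edges$score >= 0.4 & edges$gene_a %in% degs &
                 edges$gene_b %in% degs & edges$gene_a != edges$gene_b, ]
  ref_pairs <- unique(paste(pmin(ref$gene_a, ref$gene_b),
                            pmax(ref$gene_a, ref$gene_b)))
  got <- igraph::as_edgelist(g)
  got_pairs <- paste(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2]))
  expect_setequal(got_pairs, ref_pairs)
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
})

test_that("subnetwork extraction takes seeds plus first neighbors, induced", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  sub <- extract_subnetwork(star, "hub")
  expect_equal(igraph::vcount(sub), 6)

  path <- igraph::make_graph(~ a - b, b - c)
  sub2 <- extract_subnetwork(path, "a")
  expect_setequal(igraph::V(sub2)$name, c("a", "b"))
  expect_equal(igraph::ecount(sub2), 1)

  expect_warning(empty <- extract_subnetwork(path, "zzz"), "no seed")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("subnetwork extraction equals breadth-1 expansion and is idempotent", {
  withr::local_seed(37)
  for (i in 1:5) {
    rg <- random_graph(25, 0.12)
    g <- igraph::graph_from_adjacency_matrix(rg$adj, mode = "undirected")
    seeds <- sample(rg$ids, 4)
    sub <- suppressWarnings(extract_subnetwork(g, seeds))
    present <- intersect(seeds, rg$ids)
    ref_nodes <- union(present,
                       rg$ids[colSums(rg$adj[present, , drop = FALSE]) > 0])
    expect_setequal(igraph::V(sub)$name, ref_nodes)
    # induced edges: every adjacency among the node set survives
    for (u in ref_nodes) for (v in ref_nodes) {
      if (rg$adj[u, v] > 0) expect_true(igraph::are_adjacent(sub, u, v))
    }
    again <- extract_subnetwork(sub, igraph::V(sub)$name)
    expect_setequal(igraph::V(again)$name, igraph::V(sub)$name)
    expect_equal(igraph::ecount(again), igraph::ecount(sub))
  }
})

test_that("centralities are exact on hand-enumerated graphs", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("center", paste0("leaf", 1:4))
  ct <- centralities(star)
  center <- ct[ct$gene_id == "center", ]
  expect_equal(center$degree, 4L)
  expect_equal(center$betweenness, 6)      # all C(4,2) leaf pairs
  expect_equal(center$closeness, 1)
  leaves <- ct[ct$gene_id != "center", ]
  expect_equal(leaves$closeness, rep(4 / 7, 4))
  expect_equal(leaves$betweenness, rep(0, 4))

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  ct4 <- centralities(k4)
  expect_equal(ct4$betweenness, rep(0, 4))
  expect_equal(ct4$degree_rank, rep(1L, 4))
})

test_that("path-graph betweenness matches the closed form for odd lengths", {
  for (n in c(3, 5, 7)) {
    pg <- igraph::make_ring(n, circular = FALSE)
    igraph::V(pg)$name <- paste0("v", seq_len(n))
    ct <- centralities(pg)
    mid <- ct[ct$gene_id == paste0("v", (n + 1) / 2), ]
    expect_equal(mid$betweenness, (ceiling(n / 2) - 1) * floor(n / 2))
    # leaves of any tree have zero betweenness
    expect_equal(ct$betweenness[ct$gene_id %in% c("v1", paste0("v", n))],
                 c(0, 0))
  }
})

test_that("centralities handle disconnected graphs component-wise", {
  g <- igraph::make_graph(~ a - b, b - c, x - y) + igraph::vertices("iso")
  ct <- centralities(g)
  expect_equal(ct$closeness[ct$gene_id == "iso"], 0)
  expect_equal(ct$closeness[ct$gene_id == "b"], 1)        # (3-1)/2
  expect_equal(ct$closeness[ct$gene_id == "x"], 1)        # (2-1)/1
  expect_equal(ct$closeness[ct$gene_id == "a"], 2 / 3)
})

test_that("centralities match the brute-force oracle on random graphs", {
  withr::local_seed(41)
  for (i in 1:8) {
    rg <- random_graph(sample(10:30, 1), runif(1, 0.08, 0.3))
    ct <- centralities(graph_from_adj(rg$adj))
    ref <- oracle_centralities(rg$adj)
    ord <- match(ct$gene_id, rg$ids)
    expect_equal(ct$degree, as.integer(ref$degree[ord]))
    expect_equal(ct$betweenness, ref$betweenness[ord], tolerance = 1e-12)
    expect_equal(ct$closeness, ref$closeness[ord], tolerance = 1e-12)
  }
})

toy_centrality <- function(df) {
  df |>
    dplyr::mutate(degree_rank = dplyr::dense_rank(dplyr::desc(degree)),
                  betweenness_rank = dplyr::dense_rank(dplyr::desc(betweenness)),
                  closeness_rank = dplyr::dense_rank(dplyr::desc(closeness)))
}

test_that("hub calling needs two top-k metrics and candidate membership", {
  tb <- toy_centrality(tibble::tibble(
    gene_id = sprintf("n%02d", 1:30),
    degree = c(30, 29:1),          # n01 leads everything
    betweenness = c(100, 99:71),
    closeness = c(1, seq(0.9, 0.62, length.out = 29))))
  # top of all three metrics, and a candidate -> hub
  expect_true("n01" %in% hub_call(tb, candidates = "n01", k = 10)$gene_id)
  # top in two metrics but not a candidate -> not a hub
  expect_equal(nrow(hub_call(tb, candidates = "n30", k = 10)), 0)
  # top-10 in degree only -> not a hub
  tb2 <- toy_centrality(tibble::tibble(
    gene_id = c("solo", sprintf("x%02d", 1:20)),
    degree = c(50, 20:1),
    betweenness = c(0, 40:21),
    closeness = c(0.1, seq(0.9, 0.5, length.out = 20))))
  expect_equal(nrow(hub_call(tb2, candidates = "solo", k = 10)), 0)
})

test_that("dense ranking keeps ties at the cutoff", {
  tb <- toy_centrality(tibble::tibble(
    gene_id = sprintf("n%02d", 1:15),
    degree = c(rep(5, 12), 3, 2, 1),       # twelve nodes tied at the top
    betweenness = c(rep(7, 12), 3, 2, 1),  # same twelve tied again
    closeness = c(seq(0.9, 0.79, length.out = 12), 0.5, 0.4, 0.3)))
  hubs <- hub_call(tb, candidates = tb$gene_id, k = 2)
  # more than k distinct genes can be called when ties span the cutoff:
  # at k = 2 the twelve tied leaders and the second-value nodes all qualify
  expect_true(all(sprintf("n%02d", 1:13) %in% hubs$gene_id))
  expect_false(any(c("n14", "n15") %in% hubs$gene_id))
})

test_that("the cross-network degree rule needs two networks", {
  mk <- function(order_ids) {
    toy_centrality(tibble::tibble(
      gene_id = order_ids,
      degree = seq(length(order_ids), 1),
      betweenness = seq(length(order_ids), 1),
      closeness = seq(1, 0.1, length.out = length(order_ids))))
  }
  ids <- sprintf("g%02d", 1:25)
  netA <- mk(ids)                       # g01..g10 in degree top-10
  netB <- mk(c("g05", setdiff(ids, "g05")))
  netC <- mk(rev(ids))                  # g16..g25 in top-10
  out <- cross_network_degree_rule(list(A = netA, B = netB, C = netC),
                                   candidates = c("g05", "g20"))
  expect_true("g05" %in% out$gene_id)   # top-10 degree in A and B
  expect_false("g20" %in% out$gene_id)  # top-10 in C only
  # brute force over all candidates
  all_out <- cross_network_degree_rule(list(A = netA, B = netB, C = netC),
                                       candidates = ids)
  ref <- sapply(ids, function(g) {
    sum(sapply(list(netA, netB, netC),
               function(tb) tb$degree_rank[tb$gene_id == g] <= 10)) >= 2
  })
  expect_setequal(all_out$gene_id, ids[ref])
  # exclusion removes already-called hubs
  excl <- cross_network_degree_rule(list(A = netA, B = netB, C = netC),
                                    candidates = ids, exclude = "g05")
  expect_false("g05" %in% excl$gene_id)
  expect_error(cross_network_degree_rule(list(A = netA), ids), "at least 2")
})
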