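#' Build the differentially-expressed-gene PPI network
#'
#' Induces the protein-protein interaction graph on the DEG set, keeping
#' edges with interaction score at or above `score_min` (boundary included)
#' whose two endpoints are both DEGs. Self-loops and duplicate edges are
#' dropped with a message; DEGs left without any edge are excluded.
#'
#' @param edges Scored edge-list tibble (`gene_a`, `gene_b`, `score`).
#' @param degs Character vector of differentially expressed gene ids.
#' @param score_min Minimum interaction score, default 0.4.
#' @return An undirected simple `igraph` graph with edge attribute `score`.
#' @export
build_deg_network <- function(edges, degs, score_min = 0.4) {
  assert_columns(edges, c("gene_a", "gene_b", "score"), "edge list")
  keep <- edges$score >= score_min & edges$gene_a %in% degs &
    edges$gene_b %in% degs
  e <- edges[keep, ]
  loops <- e$gene_a == e$gene_b
  a <- pmin(e$gene_a, e$gene_b)
  b <- pmax(e$gene_a, e$gene_b)
  dup <- duplicated(paste(a, b, sep = "\r")) | loops
  if (any(dup)) {
    inform(sprintf("dropped %d self-loop/duplicate edge(s)", sum(dup)))
  }
  e <- tibble(gene_a = a[!dup], gene_b = b[!dup], score = e$score[!dup])
  igraph::graph_from_data_frame(e, directed = FALSE)
}

#' Extract a seed-plus-first-neighbor subnetwork
#'
#' The node set is the seeds present in the graph plus every node adjacent
#' to a seed; the edge set is all graph edges with both endpoints in that
#' node set (induced subgraph).
#'
#' @param graph An undirected `igraph` graph.
#' @param seeds Character vector of seed gene ids.
#' @return The induced `igraph` subgraph.
#' @export
extract_subnetwork <- function(graph, seeds) {
  present <- intersect(seeds, igraph::V(graph)$name)
  if (length(present) == 0) {
    warn("no seed gene is present in the graph: returning an empty graph")
    return(igraph::induced_subgraph(graph, integer(0)))
  }
  nbr_idx <- unique(unlist(igraph::adjacent_vertices(graph, present)))
  nodes <- union(present, igraph::V(graph)$name[nbr_idx])
  igraph::induced_subgraph(graph, nodes)
}

#' Degree, betweenness and closeness with dense ranks
#'
#' Degree is the incident-edge count. Betweenness is the unweighted,
#' unnormalized count over unordered node pairs (endpoints excluded) of the
#' fraction of shortest paths passing through the node. Closeness for a
#' node in a connected component of size `n_c` is
#' `(n_c - 1) / sum(distances within the component)`; isolated nodes score
#' 0. Edges are treated as unweighted for all path computations. Each
#' metric gets a dense rank (1 = highest; ties share a rank).
#'
#' @param graph An undirected `igraph` graph.
#' @return A `omx_centrality` tibble: `gene_id`, `degree`, `betweenness`,
#'   `closeness`, `degree_rank`, `betweenness_rank`, `closeness_rank`.
#' @export
centralities <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) abort("centralities need a non-empty graph")
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  comp <- igraph::components(graph)
  csize <- comp$csize[comp$membership]
  dist <- igraph::distances(graph, weights = NA)
  dist[is.infinite(dist)] <- 0  # cross-component distances do not count
  dsum <- rowSums(dist)
  clo <- ifelse(csize > 1, (csize - 1) / dsum, 0)
  out <- tibble(gene_id = igraph::V(graph)$name,
                degree = as.integer(deg),
                betweenness = unname(btw),
                closeness = unname(clo)) |>
    mutate(degree_rank = dense_rank(desc(.data$degree)),
           betweenness_rank = dense_rank(desc(.data$betweenness)),
           closeness_rank = dense_rank(desc(.data$closeness))) |>
    arrange(.data$degree_rank, .data$gene_id)
  structure(out, class = c("omx_centrality", class(out)))
}

#' Call hub genes from a centrality table
#'
#' A candidate gene is a hub when it sits in the top-`k` of at least two of
#' the three metrics. Top-`k` membership uses dense ranks, so ties at rank
#' `k` are included. Non-candidate nodes can rank arbitrarily high without
#' being called.
#'
#' @param table A `omx_centrality` tibble from [centralities()].
#' @param candidates Character vector of candidate (seed) gene ids eligible
#'   for hub status.
#' @param k Rank cutoff, default 10.
#' @return Tibble `gene_id`, `degree`, `betweenness`, `closeness`,
#'   `top_metrics` (comma-separated metrics in which the gene is top-`k`),
#'   `n_top_metrics`, restricted to called hubs.
#' @export
hub_call <- function(table, candidates, k = 10) {
  assert_columns(table, c("gene_id", "degree_rank", "betweenness_rank",
                          "closeness_rank"), "centrality table")
  hits <- table |>
    mutate(in_degree = .data$degree_rank <= k,
           in_betweenness = .data$betweenness_rank <= k,
           in_closeness = .data$closeness_rank <= k,
           n_top_metrics = .data$in_degree + .data$in_betweenness +
             .data$in_closeness)
  hits$top_metrics <- purrr::pmap_chr(
    list(hits$in_degree, hits$in_betweenness, hits$in_closeness),
    function(d, b, c) paste(c("degree", "betweenness", "closeness")[c(d, b, c)],
                            collapse = ","))
  hits |>
    filter(.data$gene_id %in% candidates, .data$n_top_metrics >= 2) |>
    select("gene_id", "degree", "betweenness", "closeness", "top_metrics",
           "n_top_metrics") |>
    arrange(desc(.data$n_top_metrics), .data$gene_id)
}

#' Cross-network degree rule for additional key genes
#'
#' A candidate gene that ranks in the degree top-`k` (dense ranks, ties
#' included) of at least two networks is returned as an additional key
#' gene, excluding genes already called hubs within a single network.
#'
#' @param tables Named list of `omx_centrality` tibbles, one per network.
#' @param candidates Character vector of eligible candidate gene ids.
#' @param k Rank cutoff, default 10.
#' @param exclude Gene ids already called hubs (excluded from the result).
#' @return Tibble `gene_id`, `networks` (comma-separated), `n_networks`.
#' @export
cross_network_degree_rule <- function(tables, candidates, k = 10,
                                      exclude = character(0)) {
  if (length(tables) < 2) abort("the cross-network rule needs at least 2 networks")
  if (is.null(names(tables))) names(tables) <- paste0("network", seq_along(tables))
  top <- purrr::imap_dfr(tables, function(tb, nm) {
    assert_columns(tb, c("gene_id", "degree_rank"), "centrality table")
    tibble(network = nm, gene_id = tb$gene_id[tb$degree_rank <= k])
  })
  top |>
    filter(.data$gene_id %in% candidates, !.data$gene_id %in% exclude) |>
    group_by(.data$gene_id) |>
    summarise(networks = paste(sort(unique(.data$network)), collapse = ","),
              n_networks = dplyr::n_distinct(.data$network), .groups = "drop") |>
    filter(.data$n_networks >= 2) |>
    arrange(desc(.data$n_networks), .data$gene_id)
}

#' Export a graph as tidy edge and node tables
#'
#' @param graph An `igraph` graph with a `score` edge attribute.
#' @return List with `edges` (`gene_a`, `gene_b`, `score`) and `nodes`
#'   (the [centralities()] table).
#' @export
tidy_graph_tables <- function(graph) {
  e <- igraph::as_data_frame(graph, what = "edges")
  edges <- tibble(gene_a = e$from, gene_b = e$to,
                  score = e$score %||% rep(NA_real_, nrow(e)))
  nodes <- if (igraph::vcount(graph) > 0) centralities(graph) else
    tibble(gene_id = character(0))
  list(edges = edges, nodes = nodes)
}
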