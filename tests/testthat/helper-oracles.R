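# Independent brute-force oracles. These recompute quantities from first
# principles and must stay free of the package's own code paths.

# step-up FDR adjustment applied literally: sort, p * n / rank, running
# minimum from the largest rank down, cap at 1, restore input order
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# textbook paired t on a vector of differences
oracle_paired_t <- function(d) {
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1))
}

# breadth-first distances and shortest-path counts from one source over an
# adjacency matrix
oracle_bfs <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  sigma <- rep(0, n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in which(adj[u, ] > 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[u] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[u] + 1) sigma[w] <- sigma[w] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# degree / betweenness / closeness by all-pairs shortest-path counting
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj > 0)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    b <- oracle_bfs(adj, s)
    dist[s, ] <- b$dist
    sigma[s, ] <- b$sigma
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq((s + 1), n)) {
        if (s == v || t == v) next
        if (is.finite(dist[s, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  clo <- numeric(n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(dist[v, ]))
    if (length(comp) > 1) {
      clo[v] <- (length(comp) - 1) / sum(dist[v, comp])
    }
  }
  list(degree = deg, betweenness = btw, closeness = clo)
}

# hypergeometric upper tail by enumerating every draw of size n from the
# background (feasible for backgrounds up to ~25 genes)
oracle_hypergeom_enum <- function(k, marked, background, n) {
  draws <- utils::combn(background, n)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# per-gene, per-sample segment assignment by scanning every segment:
# largest overlap wins, ties to the earlier start; genes as 0-based
# half-open, segments 1-based inclusive
oracle_segment_overlap <- function(segments, genes) {
  out <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    for (s in unique(segments$sample_id)) {
      best <- NULL
      best_olap <- 0
      seg_s <- segments[segments$sample_id == s &
                          segments$chromosome == g$chrom, ]
      for (si in seq_len(nrow(seg_s))) {
        seg <- seg_s[si, ]
        lo <- max(g$start, seg$start - 1)  # half-open intersection
        hi <- min(g$end, seg$end)
        olap <- hi - lo
        if (olap > best_olap ||
            (olap == best_olap && olap > 0 && !is.null(best) &&
             seg$start < best$start)) {
          best <- seg
          best_olap <- olap
        }
      }
      if (!is.null(best) && best_olap > 0) {
        out[[length(out) + 1]] <- data.frame(
          gene_id = g$gene_id, sample_id = s, log2_ratio = best$seg_mean)
      }
    }
  }
  do.call(rbind, out)
}

# random undirected simple graph as adjacency matrix + tidy edge tibble
random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  on <- up[runif(length(up)) < p]
  adj[on] <- 1L
  adj <- adj + t(adj)
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- tibble::tibble(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                          score = 1)
  list(adj = adj, edges = edges, ids = ids)
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
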