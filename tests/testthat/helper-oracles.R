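# Independent brute-force oracles for graph measures. Deliberately
# igraph-free: adjacency lists from a plain edge data frame, queue BFS, and
# betweenness by exhaustive enumeration of all simple paths.

edges_to_adj <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  ids <- sort(unique(c(as.character(edges[[1]]), as.character(edges[[2]]),
                       nodes)))
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    a <- as.character(edges[k, 1]); b <- as.character(edges[k, 2])
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

bfs_depths_oracle <- function(adj, root) {
  depth <- stats::setNames(rep(NA_real_, length(adj)), names(adj))
  depth[root] <- 0
  queue <- root
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.na(depth[v])) {
        depth[v] <- depth[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  depth
}

# All simple paths u -> v; returns list of node-id vectors.
all_simple_paths_oracle <- function(adj, u, v) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == v) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (w in adj[[last]]) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(u)
  out
}

# Normalized betweenness: for each unordered pair (s, t), every shortest
# path contributes 1/(number of shortest s-t paths) to each interior node.
betweenness_oracle <- function(adj) {
  ids <- names(adj)
  score <- stats::setNames(rep(0, length(ids)), ids)
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      paths <- all_simple_paths_oracle(adj, ids[i], ids[j])
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        score[interior] <- score[interior] + 1 / length(shortest)
      }
    }
  }
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  score / denom
}

# Small seeded connected random edge set on n nodes (for property loops).
random_connected_edges <- function(n, p = 0.45) {
  repeat {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    edges <- data.frame(from = paste0("n", pairs[keep, 1]),
                        to = paste0("n", pairs[keep, 2]))
    if (!nrow(edges)) next
    adj <- edges_to_adj(edges, nodes = paste0("n", seq_len(n)))
    if (!anyNA(bfs_depths_oracle(adj, "n1"))) return(edges)
  }
}
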