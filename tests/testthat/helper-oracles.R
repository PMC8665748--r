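# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph): path enumeration by recursive DFS,
# clustering/cliques by direct counting, Fisher p by hypergeometric
# enumeration.

# Adjacency list from an edge data frame (a1, a2, p).
oracle_adj <- function(edges) {
  nodes <- sort(unique(c(edges$a1, edges$a2)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges$a1[r]; b <- edges$a2[r]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, p = edges$p[r]))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, p = edges$p[r]))
  }
  adj
}

# Max product of probabilities over all simple paths u -> v in the graph
# minus the edge (u, v); 0 when no such path exists.
oracle_gcp <- function(edges, u, v) {
  drop <- (edges$a1 == u & edges$a2 == v) | (edges$a1 == v & edges$a2 == u)
  e2 <- edges[!drop, , drop = FALSE]
  if (nrow(e2) == 0L) return(0)
  adj <- oracle_adj(e2)
  best <- 0
  dfs <- function(node, visited, prod) {
    if (node == v) {
      best <<- max(best, prod)
      return(invisible())
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      nxt <- nb$to[r]
      if (nxt %in% visited) next
      dfs(nxt, c(visited, nxt), prod * nb$p[r])
    }
  }
  if (!u %in% names(adj) || !v %in% names(adj)) return(0)
  dfs(u, u, 1)
  best
}

# Unweighted BFS shortest path length u -> v in the graph minus (u, v).
oracle_alt_path_length <- function(edges, u, v) {
  drop <- (edges$a1 == u & edges$a2 == v) | (edges$a1 == v & edges$a2 == u)
  e2 <- edges[!drop, , drop = FALSE]
  if (nrow(e2) == 0L) return(Inf)
  adj <- oracle_adj(e2)
  if (!u %in% names(adj)) return(Inf)
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[u] <- 0
  queue <- u
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    nb <- adj[[node]]
    for (nxt in nb$to) {
      if (is.infinite(dist[nxt])) {
        dist[nxt] <- dist[node] + 1
        queue <- c(queue, nxt)
      }
    }
  }
  d <- unname(dist[v])
  if (length(d) == 0L || is.na(d)) Inf else d
}

# Per-node local clustering coefficient by neighbour-pair counting.
oracle_clustering <- function(edges) {
  nodes <- sort(unique(c(edges$a1, edges$a2)))
  has_edge <- function(a, b) {
    any((edges$a1 == a & edges$a2 == b) | (edges$a1 == b & edges$a2 == a))
  }
  vapply(nodes, function(v) {
    nb <- unique(c(edges$a2[edges$a1 == v], edges$a1[edges$a2 == v]))
    d <- length(nb)
    if (d < 2) return(0)
    pairs <- utils::combn(nb, 2)
    tri <- sum(vapply(seq_len(ncol(pairs)), function(i) {
      has_edge(pairs[1, i], pairs[2, i])
    }, logical(1)))
    2 * tri / (d * (d - 1))
  }, numeric(1))
}

# Count complete k-subgraphs by enumerating all node k-subsets.
oracle_k_cliques <- function(edges, k) {
  nodes <- sort(unique(c(edges$a1, edges$a2)))
  if (length(nodes) < k) return(0L)
  keys <- paste(pmin(edges$a1, edges$a2), pmax(edges$a1, edges$a2))
  sets <- utils::combn(nodes, k)
  cnt <- 0L
  for (i in seq_len(ncol(sets))) {
    s <- sets[, i]
    pr <- utils::combn(s, 2)
    all_in <- all(paste(pmin(pr[1, ], pr[2, ]),
                        pmax(pr[1, ], pr[2, ])) %in% keys)
    if (all_in) cnt <- cnt + 1L
  }
  cnt
}

# Two-sided Fisher exact p for a 2x2 table by summing hypergeometric
# point probabilities no larger than the observed one (with the standard
# 1 + 1e-7 relative tolerance for floating-point ties).
oracle_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]   # row 1 total
  n <- tab[2, 1] + tab[2, 2]
  kk <- tab[1, 1] + tab[2, 1]  # col 1 total
  support <- max(0, kk - n):min(kk, m)
  dens <- stats::dhyper(support, m, n, kk)
  obs <- stats::dhyper(tab[1, 1], m, n, kk)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Random simple graph with random edge probabilities.
random_graph_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  all_pairs <- utils::combn(nodes, 2)
  m <- min(n_edges, ncol(all_pairs))
  pick <- sample(ncol(all_pairs), m)
  data.frame(a1 = all_pairs[1, pick], a2 = all_pairs[2, pick],
             p = stats::runif(m, 0.05, 0.95), stringsAsFactors = FALSE)
}
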