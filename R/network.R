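# The chromatin interaction network: edge-weighted graph over anchors,
# graph connecting probability (GCP), and transitivity statistics.
#
# GCP(e) for an edge e = {u, v} with per-edge probabilities p is the
# maximum over all paths between u and v in G - e of the product of edge
# probabilities, equivalently exp(-d) where d is the shortest-path
# distance under weights -log p. Probabilities are clamped away from
# {0, 1} so the weights are finite and positive, which also guarantees
# that shortest paths are simple.

.edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Build the chromatin interaction network
#'
#' Nodes are all anchors appearing in the sample edges; each sample
#' contributes an undirected edge weighted by its predicted probability.
#' Probabilities are clamped into `[p_clamp, 1 - p_clamp]`; duplicate
#' anchor pairs are collapsed to a single edge keeping the maximum
#' probability.
#'
#' @param edges data frame with character columns `a1`, `a2` (anchor ids).
#' @param p numeric probability per edge, same length as `nrow(edges)`.
#' @param p_clamp clamping margin (default `1e-6`).
#' @return An [igraph::igraph] graph with edge attributes `p` (clamped
#'   probability) and `w` (`-log p`).
#' @export
build_network <- function(edges, p, p_clamp = 1e-6) {
  stopifnot(nrow(edges) == length(p))
  a1 <- as.character(edges$a1); a2 <- as.character(edges$a2)
  if (any(a1 == a2)) stop("self-pair sample not allowed", call. = FALSE)
  pc <- pmin(pmax(p, p_clamp), 1 - p_clamp)
  key <- .edge_key(a1, a2)
  best <- tapply(pc, key, max)
  first <- !duplicated(key)
  d <- data.frame(from = a1[first], to = a2[first],
                  p = as.numeric(best[key[first]]),
                  stringsAsFactors = FALSE)
  d$w <- -log(d$p)
  igraph::graph_from_data_frame(
    d, directed = FALSE,
    vertices = sort(unique(c(a1, a2)))
  )
}

.find_edge <- function(network, edge) {
  stopifnot(length(edge) == 2L)
  edge <- as.character(edge)
  if (!all(edge %in% igraph::V(network)$name)) {
    stop("edge endpoints not in network", call. = FALSE)
  }
  eid <- igraph::get_edge_ids(network, edge)
  if (eid == 0L) stop("edge not present in network", call. = FALSE)
  eid
}

#' Graph connecting probability of one edge
#'
#' Removes the edge and finds the alternative path between its endpoints
#' maximizing the product of edge probabilities, via a Dijkstra search on
#' `-log p` weights. A bridge edge (no alternative path) has GCP 0 and an
#' empty path.
#'
#' @param network graph from [build_network()].
#' @param edge character vector of the two endpoint anchor ids.
#' @return A `gcp_result` list: `edge`, `gcp`, and `path` (data frame of
#'   the alternative path's edges with their probabilities; 0 rows for a
#'   bridge).
#' @export
gcp <- function(network, edge) {
  eid <- .find_edge(network, edge)
  g2 <- igraph::delete_edges(network, eid)
  sp <- suppressWarnings(
    igraph::shortest_paths(g2, from = as.character(edge[1]),
                           to = as.character(edge[2]),
                           weights = igraph::E(g2)$w, output = "epath")
  )
  ep <- sp$epath[[1]]
  if (length(ep) == 0L) {
    path <- data.frame(a1 = character(), a2 = character(), p = numeric())
    return(structure(list(edge = as.character(edge), gcp = 0, path = path),
                     class = "gcp_result"))
  }
  ends <- igraph::ends(g2, ep)
  path <- data.frame(a1 = ends[, 1], a2 = ends[, 2],
                     p = igraph::E(g2)$p[as.integer(ep)],
                     stringsAsFactors = FALSE)
  val <- exp(-sum(igraph::E(g2)$w[as.integer(ep)]))
  structure(list(edge = as.character(edge), gcp = val, path = path),
            class = "gcp_result")
}

#' @export
print.gcp_result <- function(x, ...) {
  cat("GCP(", x$edge[1], ", ", x$edge[2], ") = ", format(x$gcp),
      " via ", nrow(x$path), " edge(s)\n", sep = "")
  invisible(x)
}

#' Graph connecting probability of every edge
#'
#' Applies [gcp()] edge by edge (remove the edge, run Dijkstra between its
#' endpoints on `-log p` weights).
#'
#' @param network graph from [build_network()].
#' @return Data frame with columns `a1`, `a2`, `gcp`, one row per edge in
#'   the graph's edge order.
#' @export
gcp_all <- function(network) {
  m <- igraph::ecount(network)
  ends <- igraph::ends(network, igraph::E(network))
  vals <- numeric(m)
  w <- igraph::E(network)$w
  for (i in seq_len(m)) {
    g2 <- igraph::delete_edges(network, i)
    d <- igraph::distances(g2, v = ends[i, 1], to = ends[i, 2],
                           weights = igraph::E(g2)$w)[1, 1]
    vals[i] <- if (is.infinite(d)) 0 else exp(-d)
  }
  data.frame(a1 = ends[, 1], a2 = ends[, 2], gcp = vals,
             stringsAsFactors = FALSE)
}

#' Alternative path length of an edge
#'
#' The unweighted shortest-path length (number of edges) between the
#' edge's endpoints after removing the edge; `Inf` for a bridge. A short
#' alternative path is the topological signature of a transitively formed
#' loop.
#'
#' @param network graph from [build_network()].
#' @param edge character vector of the two endpoint anchor ids.
#' @return Integer edge count or `Inf`.
#' @export
alternative_path_length <- function(network, edge) {
  eid <- .find_edge(network, edge)
  g2 <- igraph::delete_edges(network, eid)
  igraph::distances(g2, v = as.character(edge[1]),
                    to = as.character(edge[2]), weights = NA)[1, 1]
}

#' Local clustering coefficients
#'
#' For each node of degree >= 2, twice the number of triangles through the
#' node divided by `deg * (deg - 1)`; 0 for degree < 2.
#'
#' @param network graph from [build_network()].
#' @return Named numeric vector over nodes, values in `[0, 1]`.
#' @export
local_clustering_coefficients <- function(network) {
  cc <- igraph::transitivity(network, type = "local", isolates = "zero")
  names(cc) <- igraph::V(network)$name
  cc
}

#' Count complete subgraphs on k nodes
#'
#' @param network graph from [build_network()].
#' @param k clique size, `k >= 3`.
#' @return Number of k-cliques, counted as node sets.
#' @export
count_k_cliques <- function(network, k) {
  if (k < 3) stop("k must be at least 3", call. = FALSE)
  length(igraph::cliques(network, min = k, max = k))
}

#' Degree-preserving edge shuffle
#'
#' Randomizes the network by repeated double-edge swaps: two edges
#' (a,b), (c,d) are rewired to (a,d), (c,b) unless that would create a
#' self-loop or a multi-edge. The degree sequence is preserved exactly and
#' edge probabilities travel with the rewired edges. This is the null
#' model against which the clique and clustering excess of the observed
#' loop network is measured.
#'
#' @param network graph from [build_network()].
#' @param n_swaps number of attempted swaps (default `10 * ecount`).
#' @param seed integer seed.
#' @return A rewired graph with identical degree sequence.
#' @export
degree_preserving_shuffle <- function(network,
                                      n_swaps = 10 * igraph::ecount(network),
                                      seed = 1) {
  m <- igraph::ecount(network)
  if (m < 2L) {
    warning("fewer than 2 edges; returning the network unchanged")
    return(network)
  }
  set.seed(seed)
  ends <- igraph::ends(network, igraph::E(network))
  p <- igraph::E(network)$p
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) present[[.edge_key(ends[i, 1], ends[i, 2])]] <- TRUE
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(m, 2L)
    i <- ij[1]; j <- ij[2]
    a <- ends[i, 1]; b <- ends[i, 2]
    c <- ends[j, 1]; d <- ends[j, 2]
    if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    # proposed: (a,d) and (c,b)
    if (a == d || c == b) next
    k1 <- .edge_key(a, d); k2 <- .edge_key(c, b)
    if (!is.null(present[[k1]]) || !is.null(present[[k2]]) || k1 == k2) next
    rm(list = c(.edge_key(a, b), .edge_key(c, d)), envir = present)
    present[[k1]] <- TRUE; present[[k2]] <- TRUE
    ends[i, 2] <- d; ends[j, 2] <- b
    ends[i, ] <- c(min(a, d), max(a, d))
    ends[j, ] <- c(min(c, b), max(c, b))
  }
  d <- data.frame(from = ends[, 1], to = ends[, 2], p = p,
                  stringsAsFactors = FALSE)
  d$w <- -log(d$p)
  igraph::graph_from_data_frame(d, directed = FALSE,
                                vertices = igraph::V(network)$name)
}

#' Transitivity summary of a loop network
#'
#' Convenience wrapper reporting the statistics used to characterize
#' network transitivity: 3- and 4-clique counts, mean local clustering
#' coefficient, the alternative-path-length distribution over edges, and
#' the same quantities on a degree-preserving shuffle.
#'
#' @param network graph from [build_network()].
#' @param seed seed for the shuffle.
#' @return List with `n_nodes`, `n_edges`, `cliques3`, `cliques4`,
#'   `mean_clustering`, `alt_path_lengths`, and `shuffled` (same stats on
#'   the rewired null).
#' @export
network_transitivity_stats <- function(network, seed = 1) {
  apl <- function(g) {
    ends <- igraph::ends(g, igraph::E(g))
    vapply(seq_len(igraph::ecount(g)), function(i) {
      alternative_path_length(g, ends[i, ])
    }, numeric(1))
  }
  stats_of <- function(g) {
    list(cliques3 = count_k_cliques(g, 3),
         cliques4 = count_k_cliques(g, 4),
         mean_clustering = mean(local_clustering_coefficients(g)),
         alt_path_lengths = apl(g))
  }
  obs <- stats_of(network)
  shuf <- stats_of(degree_preserving_shuffle(network, seed = seed))
  c(list(n_nodes = igraph::vcount(network),
         n_edges = igraph::ecount(network)),
    obs, list(shuffled = shuf))
}
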