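# Interaction network: GCP, alternative paths, clustering, cliques,
# degree-preserving shuffle.

tri_net <- function(p = 0.5) {
  build_network(data.frame(a1 = c("u", "v", "w"), a2 = c("v", "w", "u")),
                rep(p, 3))
}

test_that("network construction clamps, dedupes and rejects self-pairs", {
  net <- build_network(data.frame(a1 = c("a", "a", "c"),
                                  a2 = c("b", "b", "d")),
                       c(0.2, 0.7, 0))
  expect_equal(igraph::ecount(net), 2L)
  ab <- igraph::E(net)$p[igraph::get_edge_ids(net, c("a", "b"))]
  expect_equal(ab, 0.7)             # duplicate pair keeps max probability
  cd <- igraph::E(net)$p[igraph::get_edge_ids(net, c("c", "d"))]
  expect_equal(cd, 1e-6)            # p = 0 clamped
  expect_error(build_network(data.frame(a1 = "x", a2 = "x"), 0.5), "self")
  # 3 samples on 4 anchors -> 4 nodes, 3 edges
  net2 <- build_network(data.frame(a1 = c("a", "b", "c"),
                                   a2 = c("b", "c", "d")), rep(0.5, 3))
  expect_equal(igraph::vcount(net2), 4L)
  expect_equal(igraph::ecount(net2), 3L)
})

test_that("GCP on canonical small graphs matches hand enumeration", {
  net <- tri_net(0.5)
  r <- gcp(net, c("u", "v"))
  expect_equal(r$gcp, 0.25)         # single alternative path u-w-v
  expect_equal(nrow(r$path), 2L)
  expect_equal(prod(r$path$p), r$gcp)

  g4 <- build_network(data.frame(a1 = c("a", "b", "c", "d"),
                                 a2 = c("b", "c", "d", "a")), rep(0.9, 4))
  expect_equal(gcp(g4, c("a", "b"))$gcp, 0.9^3, tolerance = 1e-12)

  # bridge edge: no alternative path
  bridge <- build_network(data.frame(a1 = "a", a2 = "b"), 0.5)
  rb <- gcp(bridge, c("a", "b"))
  expect_equal(rb$gcp, 0)
  expect_equal(nrow(rb$path), 0L)

  # p = 1 clamps; alternative path of two edges stays ~1
  g1 <- tri_net(1)
  expect_equal(gcp(g1, c("u", "v"))$gcp, 1, tolerance = 1e-5)

  expect_error(gcp(net, c("u", "zz")), "not in network")
  expect_error(gcp(build_network(data.frame(a1 = c("u", "w"),
                                            a2 = c("v", "x")),
                                 c(0.5, 0.5)), c("u", "w")), "not present")
})

test_that("gcp_all agrees with per-edge gcp and known symmetric cases", {
  net <- tri_net(0.5)
  tab <- gcp_all(net)
  expect_equal(tab$gcp, rep(0.25, 3))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$gcp[i], gcp(net, c(tab$a1[i], tab$a2[i]))$gcp)
  }
  star <- build_network(data.frame(a1 = rep("hub", 4),
                                   a2 = paste0("s", 1:4)), rep(0.8, 4))
  expect_equal(gcp_all(star)$gcp, rep(0, 4))   # every edge is a bridge
  path3 <- build_network(data.frame(a1 = c("a", "b"), a2 = c("b", "c")),
                         c(0.5, 0.5))
  expect_equal(gcp_all(path3)$gcp, rep(0, 2))
})

test_that("GCP equals the brute-force maximum over simple paths", {
  for (i in 1:40) {
    n_nodes <- sample(4:10, 1)
    edges <- random_graph_edges(n_nodes, sample(4:20, 1), seed = 1000 + i)
    net <- build_network(edges[, c("a1", "a2")], edges$p)
    tab <- gcp_all(net)
    lut <- stats::setNames(edges$p, paste(pmin(edges$a1, edges$a2),
                                          pmax(edges$a1, edges$a2)))
    for (r in seq_len(nrow(tab))) {
      expect_equal(tab$gcp[r], oracle_gcp(edges, tab$a1[r], tab$a2[r]),
                   tolerance = 1e-9)
    }
  }
})

test_that("log-domain value matches the product over the returned path", {
  for (i in 1:10) {
    edges <- random_graph_edges(8, 14, seed = 2000 + i)
    net <- build_network(edges[, c("a1", "a2")], edges$p)
    ends <- igraph::ends(net, igraph::E(net))
    for (r in seq_len(nrow(ends))) {
      res <- gcp(net, ends[r, ])
      if (nrow(res$path)) {
        expect_equal(res$gcp, prod(res$path$p), tolerance = 1e-12)
      } else {
        expect_equal(res$gcp, 0)
      }
    }
  }
})

test_that("GCP is monotone under edge addition and positivity matches
           finite alternative paths", {
  set.seed(99)
  for (i in 1:15) {
    edges <- random_graph_edges(7, 9, seed = 3000 + i)
    net <- build_network(edges[, c("a1", "a2")], edges$p)
    before <- gcp_all(net)
    # add a fresh random edge between non-adjacent nodes
    nodes <- igraph::V(net)$name
    pairs <- t(utils::combn(nodes, 2))
    keys <- paste(pmin(edges$a1, edges$a2), pmax(edges$a1, edges$a2))
    free <- pairs[!paste(pmin(pairs[, 1], pairs[, 2]),
                         pmax(pairs[, 1], pairs[, 2])) %in% keys, ,
                  drop = FALSE]
    if (nrow(free) == 0L) next
    pick <- free[sample(nrow(free), 1), ]
    edges2 <- rbind(edges, data.frame(a1 = pick[1], a2 = pick[2],
                                      p = runif(1, 0.05, 0.95)))
    net2 <- build_network(edges2[, c("a1", "a2")], edges2$p)
    after <- gcp_all(net2)
    lut <- stats::setNames(after$gcp, paste(after$a1, after$a2))
    expect_true(all(lut[paste(before$a1, before$a2)] >=
                      before$gcp - 1e-12))
    # gcp > 0 <=> finite alternative path length
    for (r in seq_len(nrow(before))) {
      apl <- alternative_path_length(net, c(before$a1[r], before$a2[r]))
      expect_equal(before$gcp[r] > 0, is.finite(apl))
    }
  }
})

test_that("alternative path lengths match BFS and the two-path example", {
  # direct edge n1-n4 plus paths n1-n2-n3-n4 and n1-n5-n4
  edges <- data.frame(
    a1 = c("n1", "n1", "n2", "n3", "n1", "n5"),
    a2 = c("n4", "n2", "n3", "n4", "n5", "n4"),
    p = rep(0.5, 6)
  )
  net <- build_network(edges[, c("a1", "a2")], edges$p)
  expect_equal(alternative_path_length(net, c("n1", "n4")), 2)
  expect_equal(alternative_path_length(tri_net(), c("u", "v")), 2)
  iso <- build_network(data.frame(a1 = "a", a2 = "b"), 0.5)
  expect_equal(alternative_path_length(iso, c("a", "b")), Inf)
  for (i in 1:20) {
    e <- random_graph_edges(8, sample(5:16, 1), seed = 4000 + i)
    net <- build_network(e[, c("a1", "a2")], e$p)
    ends <- igraph::ends(net, igraph::E(net))
    for (r in seq_len(nrow(ends))) {
      expect_equal(alternative_path_length(net, ends[r, ]),
                   oracle_alt_path_length(e, ends[r, 1], ends[r, 2]))
    }
  }
})

test_that("clustering coefficients and clique counts match enumeration", {
  net <- tri_net()
  expect_equal(unname(local_clustering_coefficients(net)), rep(1, 3))
  star <- build_network(data.frame(a1 = rep("hub", 4),
                                   a2 = paste0("s", 1:4)), rep(0.5, 4))
  expect_equal(unname(local_clustering_coefficients(star)["hub"]), 0)
  # node with 3 neighbours and one closed neighbour pair -> 1/3
  e <- data.frame(a1 = c("x", "x", "x", "a"), a2 = c("a", "b", "c", "b"),
                  p = rep(0.5, 4))
  net13 <- build_network(e[, c("a1", "a2")], e$p)
  expect_equal(unname(local_clustering_coefficients(net13)["x"]), 1 / 3)

  expect_equal(count_k_cliques(net, 3), 1L)
  k4 <- build_network(data.frame(a1 = c("a", "a", "a", "b", "b", "c"),
                                 a2 = c("b", "c", "d", "c", "d", "d")),
                      rep(0.5, 6))
  expect_equal(count_k_cliques(k4, 3), 4L)
  expect_equal(count_k_cliques(k4, 4), 1L)
  expect_equal(count_k_cliques(star, 3), 0L)
  expect_error(count_k_cliques(net, 2), "at least 3")

  for (i in 1:20) {
    e <- random_graph_edges(sample(5:12, 1), sample(6:22, 1), 5000 + i)
    net <- build_network(e[, c("a1", "a2")], e$p)
    expect_equal(unname(local_clustering_coefficients(net)
                        [sort(igraph::V(net)$name)]),
                 unname(oracle_clustering(e)), tolerance = 1e-12)
    expect_equal(count_k_cliques(net, 3), oracle_k_cliques(e, 3))
    expect_equal(count_k_cliques(net, 4), oracle_k_cliques(e, 4))
  }
})

test_that("degree-preserving shuffle keeps degrees, simplicity and seeds", {
  fx <- small_prepared()
  pos <- fx$prep$samples[fx$prep$samples$label == "positive", ]
  net <- build_network(pos[, c("a1", "a2")], rep(0.5, nrow(pos)))
  sh1 <- degree_preserving_shuffle(net, seed = 7)
  sh2 <- degree_preserving_shuffle(net, seed = 7)
  deg <- function(g) sort(igraph::degree(g))
  expect_equal(deg(sh1), deg(net))
  expect_true(igraph::is_simple(sh1))
  expect_identical(igraph::as_edgelist(sh1), igraph::as_edgelist(sh2))
  expect_false(identical(sort(apply(igraph::as_edgelist(sh1), 1,
                                    paste, collapse = "|")),
                         sort(apply(igraph::as_edgelist(net), 1,
                                    paste, collapse = "|"))))
  # probabilities travel with edges: multiset of p preserved
  expect_equal(sort(igraph::E(sh1)$p), sort(igraph::E(net)$p))

  # a triangle is the unique simple graph on degrees (2,2,2) over 3 nodes
  tri <- tri_net()
  sht <- degree_preserving_shuffle(tri, n_swaps = 100, seed = 1)
  expect_equal(sort(apply(igraph::as_edgelist(sht), 1,
                          function(r) paste(sort(r), collapse = "|"))),
               sort(apply(igraph::as_edgelist(tri), 1,
                          function(r) paste(sort(r), collapse = "|"))))
  expect_warning(degree_preserving_shuffle(
    build_network(data.frame(a1 = "a", a2 = "b"), 0.5)), "fewer than 2")
})
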