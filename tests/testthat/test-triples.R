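# Transitive triples, cluster assignment, colocalization test and
# frequency profiles.

mk_loopset <- function(a1, a2, orientation) {
  data.frame(a1 = a1, a2 = a2, orientation = orientation,
             stringsAsFactors = FALSE)
}

test_that("triple detection requires a tandem edge with two bridges", {
  loops <- mk_loopset(c("A", "A", "B"), c("B", "C", "C"),
                      c("tandem", "convergent", "convergent"))
  tr <- find_transitive_triples(loops)
  expect_equal(nrow(tr), 1L)
  expect_equal(unlist(tr[1, ], use.names = FALSE), c("A", "B", "C"))

  # only one bridge -> nothing
  one <- mk_loopset(c("A", "A"), c("B", "C"), c("tandem", "convergent"))
  expect_equal(nrow(find_transitive_triples(one)), 0L)

  # two alternative third anchors -> two triples
  two <- mk_loopset(c("A", "A", "B", "A", "B"),
                    c("B", "C", "C", "D", "D"),
                    c("tandem", rep("convergent", 4)))
  expect_equal(nrow(find_transitive_triples(two)), 2L)

  # tandem bridges only count in permissive mode; there, every tandem
  # edge of the triangle is bridged by the other two (3 distinct triples)
  perm <- mk_loopset(c("A", "A", "B"), c("B", "C", "C"),
                     c("tandem", "tandem", "tandem"))
  expect_equal(nrow(find_transitive_triples(perm)), 0L)
  expect_equal(nrow(find_transitive_triples(perm,
                                            bridge_orientation = "any")), 3L)
})

test_that("triple enumeration matches brute force on a simulated network", {
  fx <- small_prepared()
  pos <- fx$prep$samples[fx$prep$samples$label == "positive", ]
  tr <- find_transitive_triples(pos)
  # brute force over all anchor triples
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tand <- key(pos$a1, pos$a2)[pos$orientation == "tandem"]
  conv <- key(pos$a1, pos$a2)[pos$orientation == "convergent"]
  anchors <- unique(c(pos$a1, pos$a2))
  brute <- 0L
  tpos <- pos[pos$orientation == "tandem", ]
  for (i in seq_len(nrow(tpos))) {
    for (cc in setdiff(anchors, c(tpos$a1[i], tpos$a2[i]))) {
      if (key(tpos$a1[i], cc) %in% conv && key(tpos$a2[i], cc) %in% conv) {
        brute <- brute + 1L
      }
    }
  }
  expect_equal(nrow(tr), brute)
  expect_gt(nrow(tr), 0L)  # the generator must actually produce triples
})

test_that("cluster members map to the nearest anchor within 5 kb", {
  anchors <- data.frame(chrom = "chr1",
                        start = c(10000L, 30000L, 60000L),
                        end = c(10019L, 30019L, 60019L),
                        anchor_id = c("A", "B", "C"),
                        stringsAsFactors = FALSE)
  cl <- list(
    data.frame(chrom = "chr1", start = c(12500, 29500, 59500),
               end = c(13500, 30500, 60500)),   # 3 kb, 0 kb, 0 kb away
    data.frame(chrom = "chr1", start = c(16500, 29500),
               end = c(17500, 30500)),          # first member 7 kb away
    data.frame(chrom = "chr2", start = c(100, 200), end = c(150, 250))
  )
  asg <- assign_clusters_to_anchors(cl, anchors, max_distance = 5000)
  expect_length(asg, 1L)               # cluster 2 and 3 lose members
  expect_equal(asg[[1]], c("A", "B", "C"))

  # 6 kb member dropped, 3 kb kept
  cl2 <- list(data.frame(chrom = "chr1", start = c(12500, 35500),
                         end = c(13500, 36500)))
  expect_length(assign_clusters_to_anchors(cl2, anchors), 0L)

  # equidistant between B and C: lower-coordinate anchor wins
  a2 <- data.frame(chrom = "chr1", start = c(10000L, 30000L, 60000L),
                   end = c(10020L, 30020L, 60020L),
                   anchor_id = c("A", "B", "C"), stringsAsFactors = FALSE)
  mid <- (30010 + 60010) / 2          # exactly between B and C
  cl3 <- list(data.frame(chrom = "chr1", start = c(9510, mid - 500),
                         end = c(10510, mid + 500)))
  asg3 <- assign_clusters_to_anchors(cl3, a2, max_distance = 2e4)
  expect_equal(asg3[[1]], c("A", "B"))
})

test_that("support counting and the 20-cluster validation threshold", {
  triples <- data.frame(a = c("A", "X"), b = c("B", "Y"), c = c("C", "Z"),
                        stringsAsFactors = FALSE)
  abc <- list(c("A", "B", "C"))
  clusters <- c(rep(abc, 25), list(c("A", "B")), rep(list(c("X", "Y", "Z")),
                                                     19))
  out <- triple_cluster_support(triples, clusters, min_count = 20)
  expect_equal(out$support_count, c(25L, 19L))
  expect_equal(out$validated, c(TRUE, FALSE))
  none <- triple_cluster_support(triples, list(), min_count = 20)
  expect_equal(none$support_count, c(0L, 0L))
  expect_false(any(none$validated))
})

test_that("Fisher p matches hypergeometric enumeration and known tables", {
  mk <- function(n11, n12, n21, n22) {
    matrix(c(n11, n12, n21, n22), 2, byrow = TRUE)
  }
  expect_equal(stats::fisher.test(mk(10, 0, 0, 10))$p.value, 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(stats::fisher.test(mk(5, 5, 5, 5))$p.value, 1)
  expect_equal(stats::fisher.test(mk(1, 0, 0, 1))$p.value, 1)
  set.seed(21)
  for (i in 1:200) {
    tab <- mk(sample(0:15, 1), sample(0:15, 1), sample(0:15, 1),
              sample(0:15, 1))
    if (sum(tab) == 0) next
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("colocalization test builds the right table and odds ratio", {
  pos <- data.frame(a1 = c("A", "D", "F"), a2 = c("B", "E", "G"),
                    stringsAsFactors = FALSE)
  neg <- data.frame(a1 = c("P", "R"), a2 = c("Q", "S"),
                    stringsAsFactors = FALSE)
  vt <- data.frame(a = c("A", "P"), b = c("B", "Q"), c = c("C", "T"),
                   support_count = c(30L, 5L), validated = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  ct <- colocalization_test(pos, neg, vt)
  expect_equal(unname(ct$table["positive", "valid"]), 1)
  expect_equal(unname(ct$table["negative", "valid"]), 0)
  expect_equal(ct$p_value, stats::fisher.test(ct$table)$p.value)
  # Haldane correction on the zero cell
  expect_equal(ct$odds_ratio, (1.5 * 2.5) / (2.5 * 0.5))
  expect_error(colocalization_test(pos[0, ], neg, vt), "required")
})

test_that("frequency profiles count monotonically by threshold", {
  loops <- data.frame(
    orientation = c("convergent", "convergent", "tandem"),
    frequency = c(10L, 10L, 2L)
  )
  prof <- frequency_threshold_profile(loops, c(1, 5, 6, 11))
  expect_equal(prof$n_convergent, c(2L, 2L, 2L, 0L))
  expect_equal(prof$n_tandem, c(1L, 0L, 0L, 0L))
  expect_equal(prof$proportion_convergent[1:2], c(2 / 3, 1))
  expect_true(is.na(prof$proportion_convergent[4]))
  expect_true(all(diff(prof$n_convergent) <= 0))
  expect_error(frequency_threshold_profile(
    data.frame(orientation = "tandem", frequency = NA_integer_), 1),
    "frequency")
})
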