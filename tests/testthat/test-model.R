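# Two-stage forest: out-of-fold probabilities, GCP feature, prediction,
# cross-validation, importances, ablation.

fast_params <- forest_params(num_trees = 100)

test_that("metrics behave on perfect, inverted and degenerate scorers", {
  lab <- c(0, 0, 1, 1)
  m <- compute_metrics(lab, c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unname(m["auroc"]), 1)
  expect_equal(unname(m["aupr"]), 1)
  expect_equal(unname(m["accuracy"]), 1)
  expect_equal(unname(m["f1"]), 1)
  m2 <- compute_metrics(lab, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(m2["auroc"]), 0)
  expect_true(is.na(compute_metrics(c(1, 1), c(0.5, 0.6))["auroc"]))
})

test_that("stage-one fit separates a separable fixture and is seeded", {
  fx <- separable_fixture(n = 60, seed = 4)
  s1 <- train_stage1(fx$x, fx$labels, fast_params, seed = 3)
  expect_gte(compute_metrics(fx$labels, s1$oof)["auroc"], 0.99)
  s1b <- train_stage1(fx$x, fx$labels, fast_params, seed = 3)
  expect_identical(s1$oof, s1b$oof)
  expect_error(train_stage1(fx$x, rep(1, 60), fast_params, 1),
               "single class")
})

test_that("out-of-fold probabilities differ from in-sample predictions", {
  # memorizable noise: in-sample forest predictions track the labels,
  # out-of-fold ones cannot
  set.seed(8)
  n <- 80
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  labels <- rep(c(0L, 1L), n / 2)
  s1 <- train_stage1(x, labels, fast_params, seed = 5)
  insample <- predict(s1$forest, data = x, num.threads = 1)$predictions[, "1"]
  in_auc <- compute_metrics(labels, insample)["auroc"]
  oof_auc <- compute_metrics(labels, s1$oof)["auroc"]
  expect_gt(in_auc, 0.95)           # the forest memorizes
  expect_lt(oof_auc, 0.75)          # held-out rows are not memorized
})

test_that("GCP feature aligns with samples and handles degenerate nets", {
  edges <- data.frame(a1 = c("u", "v", "w"), a2 = c("v", "w", "u"))
  g <- add_gcp_feature(edges, c(0.5, 0.5, 0.5))
  expect_equal(g, rep(0.25, 3))
  perm <- c(3, 1, 2)
  expect_equal(add_gcp_feature(edges[perm, ], rep(0.5, 3)), g[perm])
  # disjoint pairs: every edge a bridge -> all zero
  iso <- data.frame(a1 = c("a", "c"), a2 = c("b", "d"))
  expect_equal(add_gcp_feature(iso, c(0.9, 0.9)), c(0, 0))
})

test_that("two-stage training stores the oof-weighted network and seeds", {
  fx <- small_prepared()
  feats <- assemble_feature_matrix(fx$prep)
  x <- feats$x; labels <- feats$labels
  edges <- fx$prep$samples[, c("a1", "a2")]
  m1 <- train_two_stage(x, labels, edges, fast_params, seed = 2)
  m2 <- train_two_stage(x, labels, edges, fast_params, seed = 2)
  expect_identical(m1$oof, m2$oof)
  expect_identical(m1$train_gcp, m2$train_gcp)
  expect_equal(length(m1$train_gcp), nrow(x))
  expect_error(train_two_stage(cbind(x, GCP = 0), labels, edges,
                               fast_params, 1), "GCP")
  # stage-2 input width = stage-1 width + 1
  expect_equal(m1$stage2$num.independent.variables,
               m1$stage1$num.independent.variables + 1L)
})

test_that("prediction scores new edges on the combined network", {
  # training network: a high-probability path u-v-w plus filler edges;
  # new edge (u,w) closes the triangle and must get positive GCP
  fx <- separable_fixture(n = 40, seed = 9)
  edges <- fx$edges
  edges$a1[1:2] <- c("u", "v"); edges$a2[1:2] <- c("v", "w")
  fx$x[1:2, 1] <- 10; labels <- fx$labels; labels[1:2] <- 1L
  m <- train_two_stage(fx$x, labels, edges, fast_params, seed = 3)
  newx <- fx$x[c(3, 4), , drop = FALSE]
  newx[1, 1] <- 10                    # looks positive to stage 1
  det <- predict(m, newx, data.frame(a1 = c("u", "x1"), a2 = c("w", "x2")),
                 type = "detail")
  expect_gt(det$gcp[1], 0)            # closes the u-v-w triangle
  expect_equal(det$gcp[2], 0)         # never-seen anchors
  expect_true(all(det$final >= 0 & det$final <= 1))
  expect_equal(length(predict(m, newx[0, , drop = FALSE],
                              data.frame(a1 = character(),
                                         a2 = character()))), 0L)
})

test_that("cross-validation folds are disjoint, complete and honor chromosomes", {
  n <- 45
  fold_w <- loopgcp:::.fold_assignment(n, 5, seed = 2,
                                       labels = rep(c(0, 1), length.out = n))
  expect_equal(sort(unique(fold_w)), 1:5)
  expect_equal(length(fold_w), n)
  chrom <- sample(paste0("chr", 1:4), n, replace = TRUE)
  fold_c <- loopgcp:::.fold_assignment(n, 4, seed = 2, groups = chrom)
  for (f in unique(fold_c)) {
    expect_length(intersect(chrom[fold_c == f], chrom[fold_c != f]), 0L)
  }
})

test_that("within-cell CV is near-perfect on separable data and the
           two-stage report is well-formed", {
  fx <- separable_fixture(n = 80, seed = 5)
  ev <- cross_validate(fx$x, fx$labels, fx$edges, k = 5,
                       params = fast_params, seed = 6)
  expect_equal(nrow(ev$per_fold), 10L)   # 5 folds x 2 models
  expect_true(all(ev$per_fold$auroc >= 0 & ev$per_fold$auroc <= 1))
  expect_gte(ev$summary$auroc[ev$summary$model == "basic"], 0.95)
  expect_gte(ev$summary$auroc[ev$summary$model == "final"], 0.95)
})

test_that("across-chromosome CV reduces folds and never splits a chromosome", {
  fx <- small_prepared()
  feats <- assemble_feature_matrix(fx$prep)
  keep <- seq_len(nrow(feats$x))
  expect_warning(
    ev <- cross_validate(feats$x, feats$labels,
                         fx$prep$samples[, c("a1", "a2")],
                         chrom = fx$prep$samples$chrom,
                         scheme = "across_chromosome", k = 10,
                         params = fast_params, seed = 4),
    "reducing folds"
  )
  expect_equal(ev$k, 2L)               # fixture has two chromosomes
  expect_true(all(is.finite(ev$per_fold$auroc)))
})

test_that("across-cell evaluation trains on one set and tests the other", {
  fx1 <- separable_fixture(n = 60, seed = 11)
  fx2 <- separable_fixture(n = 40, seed = 12)
  fx2$edges$a1 <- paste0("cell2_", fx2$edges$a1)
  fx2$edges$a2 <- paste0("cell2_", fx2$edges$a2)
  ev <- cross_validate(fx1$x, fx1$labels, fx1$edges,
                       scheme = "across_cell", params = fast_params,
                       seed = 1,
                       test = list(x = fx2$x, labels = fx2$labels,
                                   edges = fx2$edges))
  expect_equal(ev$k, 1L)
  expect_gte(ev$summary$auroc[ev$summary$model == "final"], 0.95)
})

test_that("importances are normalized and motif aggregation conserves mass", {
  fx <- small_prepared()
  feats <- assemble_feature_matrix(fx$prep)
  m <- train_two_stage(feats$x, feats$labels,
                       fx$prep$samples[, c("a1", "a2")], fast_params,
                       seed = 13)
  raw <- feature_importances(m, aggregate_motif = FALSE)
  expect_equal(sum(raw$basic$importance), 1, tolerance = 1e-9)
  expect_equal(sum(raw$final$importance), 1, tolerance = 1e-9)
  expect_true(all(raw$final$importance >= 0))
  agg <- feature_importances(m, aggregate_motif = TRUE)
  expect_equal(sum(agg$final$importance), 1, tolerance = 1e-9)
  expect_true("motif_sequence" %in% agg$final$feature)
  expect_true("GCP" %in% agg$final$feature)
  expect_false("GCP" %in% agg$basic$feature)
})

test_that("ablation returns both stages per combination and is seeded", {
  fx <- small_prepared()
  feats <- assemble_feature_matrix(fx$prep)
  combos <- list("base", c("base", "inbetween"))
  ab1 <- ablation(feats$x, feats$labels, fx$prep$samples[, c("a1", "a2")],
                  combos = combos, k = 2, params = fast_params, seed = 3)
  ab2 <- ablation(feats$x, feats$labels, fx$prep$samples[, c("a1", "a2")],
                  combos = combos, k = 2, params = fast_params, seed = 3)
  expect_identical(ab1, ab2)
  expect_equal(ab1$combination, c("base", "base+inbetween"))
  expect_true(all(c("basic_auroc", "final_auroc") %in% names(ab1)))
  expect_error(ablation(feats$x, feats$labels,
                        fx$prep$samples[, c("a1", "a2")],
                        combos = list(character(0)), k = 2,
                        params = fast_params, seed = 1), "combination")
})
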