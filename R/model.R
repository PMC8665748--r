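# Two-stage random-forest training and evaluation. Stage one scores
# candidate loops from the base feature matrix; its OUT-OF-FOLD predicted
# probabilities weight the interaction network from which GCP is computed;
# stage two retrains on the base features plus GCP. Out-of-fold
# probabilities are used deliberately: in-sample forest predictions are
# nearly equal to the labels and would leak them into the network feature.

#' Random-forest hyperparameters
#'
#' @param num_trees trees per forest (default 500).
#' @param mtry features tried per split (default: `ranger`'s square-root
#'   rule).
#' @param min_node_size minimal node size (default: `ranger`'s default for
#'   probability forests).
#' @return A `forest_params` list.
#' @export
forest_params <- function(num_trees = 500, mtry = NULL,
                          min_node_size = NULL) {
  structure(list(num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size),
            class = "forest_params")
}

.fit_forest <- function(x, labels, params, seed) {
  ranger::ranger(
    x = x, y = factor(labels, levels = c(0, 1)),
    probability = TRUE, num.trees = params$num_trees, mtry = params$mtry,
    min.node.size = params$min_node_size, importance = "impurity",
    seed = seed, num.threads = 1, verbose = FALSE
  )
}

.predict_forest <- function(fit, x) {
  as.numeric(stats::predict(fit, data = x, num.threads = 1,
                            verbose = FALSE)$predictions[, "1"])
}

# Fold assignment. Stratified by label (default), or by group so that all
# rows of a group land in the same fold (chromosome-level splits).
.fold_assignment <- function(n, k, seed, labels = NULL, groups = NULL) {
  set.seed(seed)
  fold <- integer(n)
  if (!is.null(groups)) {
    u <- sample(unique(groups))
    gf <- rep_len(seq_len(k), length(u))
    fold <- gf[match(groups, u)]
  } else if (!is.null(labels)) {
    for (lv in unique(labels)) {
      ix <- which(labels == lv)
      fold[ix[sample.int(length(ix))]] <- rep_len(seq_len(k), length(ix))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Classification metrics for probabilistic predictions
#'
#' AUROC (via [pROC::auc]), AUPR (average precision, i.e. step-function
#' integration of the precision-recall curve), and accuracy and F1 at the
#' 0.5 threshold.
#'
#' @param labels 0/1 vector.
#' @param scores predicted positive-class probabilities.
#' @return Named numeric vector `auroc`, `aupr`, `accuracy`, `f1`.
#' @export
compute_metrics <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (length(unique(labels)) < 2L) {
    return(c(auroc = NA_real_, aupr = NA_real_, accuracy = NA_real_,
             f1 = NA_real_))
  }
  auroc <- as.numeric(pROC::auc(
    response = factor(labels, levels = c(0, 1)), predictor = scores,
    levels = c("0", "1"), direction = "<", quiet = TRUE
  ))
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  aupr <- sum(precision * diff(c(0, recall)))
  pred <- as.integer(scores >= 0.5)
  accuracy <- mean(pred == labels)
  tp2 <- sum(pred == 1 & labels == 1)
  f1 <- if (2 * tp2 + sum(pred == 1 & labels == 0) +
              sum(pred == 0 & labels == 1) == 0) 0 else
    2 * tp2 / (2 * tp2 + sum(pred == 1 & labels == 0) +
                 sum(pred == 0 & labels == 1))
  c(auroc = auroc, aupr = aupr, accuracy = accuracy, f1 = f1)
}

#' Train the stage-one (basic) forest
#'
#' Fits a probability forest on the base feature matrix and computes
#' out-of-fold predicted positive-class probabilities for every training
#' row via internal k-fold refitting. The out-of-fold probabilities, not
#' the in-sample ones, later weight the interaction network.
#'
#' @param x base feature matrix (no GCP column).
#' @param labels 0/1 vector.
#' @param params [forest_params()].
#' @param seed integer seed; everything downstream is reproducible from it.
#' @param oof_k internal folds for out-of-fold probabilities (default 5).
#' @return List with `forest`, `oof` (per-row probabilities), `oof_folds`,
#'   `params`, `seed`.
#' @export
train_stage1 <- function(x, labels, params = forest_params(), seed = 1,
                         oof_k = 5) {
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  n <- nrow(x)
  fold <- .fold_assignment(n, oof_k, seed, labels = labels)
  oof <- numeric(n)
  for (f in seq_len(oof_k)) {
    te <- fold == f
    fit <- .fit_forest(x[!te, , drop = FALSE], labels[!te], params,
                       seed + f)
    oof[te] <- .predict_forest(fit, x[te, , drop = FALSE])
  }
  forest <- .fit_forest(x, labels, params, seed)
  list(forest = forest, oof = oof, oof_folds = fold, params = params,
       seed = seed)
}

#' GCP column for a set of samples
#'
#' Builds the interaction network from all sample edges (both classes)
#' weighted by the given probabilities, computes GCP for every edge and
#' returns the values aligned to the sample order. Samples repeating the
#' same anchor pair share the pair's edge (which keeps the maximum
#' probability) and therefore the same GCP.
#'
#' @param edges data frame with columns `a1`, `a2`, one row per sample.
#' @param probabilities predicted probability per sample.
#' @param p_clamp clamping margin for [build_network()].
#' @return Numeric GCP vector, one value per sample row.
#' @export
add_gcp_feature <- function(edges, probabilities, p_clamp = 1e-6) {
  net <- build_network(edges, probabilities, p_clamp)
  tab <- gcp_all(net)
  lut <- stats::setNames(tab$gcp, .edge_key(tab$a1, tab$a2))
  as.numeric(lut[.edge_key(as.character(edges$a1),
                           as.character(edges$a2))])
}

#' Train the full two-stage model
#'
#' Stage one per [train_stage1()]; the out-of-fold probabilities define
#' the training network and its GCP column; stage two refits the forest on
#' the base features plus GCP.
#'
#' @param x base feature matrix (must not contain a GCP column).
#' @param labels 0/1 vector.
#' @param edges anchor-pair data frame aligned with the rows of `x`.
#' @param params [forest_params()].
#' @param seed integer seed.
#' @param oof_k internal folds for the stage-one probabilities.
#' @param p_clamp probability clamp for the network.
#' @return A `two_stage_model` object.
#' @export
train_two_stage <- function(x, labels, edges, params = forest_params(),
                            seed = 1, oof_k = 5, p_clamp = 1e-6) {
  if ("GCP" %in% colnames(x)) {
    stop("x must not already contain a GCP column", call. = FALSE)
  }
  s1 <- train_stage1(x, labels, params, seed, oof_k)
  gcp_col <- add_gcp_feature(edges, s1$oof, p_clamp)
  x2 <- cbind(x, GCP = gcp_col)
  stage2 <- .fit_forest(x2, labels, params, seed + 500000L)
  structure(
    list(stage1 = s1$forest, stage2 = stage2, oof = s1$oof,
         train_edges = edges[, c("a1", "a2")], train_gcp = gcp_col,
         params = params, seed = seed, p_clamp = p_clamp,
         feature_names = colnames(x)),
    class = "two_stage_model"
  )
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat("two_stage_model:", length(x$oof), "training samples,",
      length(x$feature_names), "base features,",
      x$params$num_trees, "trees per stage\n")
  invisible(x)
}

#' Predict loop probabilities for new samples
#'
#' Stage one scores the new samples; a combined network -- training edges
#' at their stored out-of-fold probabilities plus new edges at their
#' stage-one probabilities -- supplies GCP for the new edges; stage two
#' emits the final probability.
#'
#' @param object a `two_stage_model`.
#' @param x base feature matrix for the new samples.
#' @param edges anchor pairs aligned with the rows of `x`.
#' @param type `"final"` for the final probability vector, `"detail"` for
#'   a data frame with `stage1`, `gcp` and `final` columns.
#' @param include_train_edges whether the GCP network includes the
#'   training edges (default) or only the new edges.
#' @param ... unused.
#' @return Numeric probabilities, or a data frame when `type = "detail"`.
#' @export
predict.two_stage_model <- function(object, x, edges,
                                    type = c("final", "detail"),
                                    include_train_edges = TRUE, ...) {
  type <- match.arg(type)
  if (nrow(x) == 0L) {
    out <- data.frame(stage1 = numeric(), gcp = numeric(),
                      final = numeric())
    return(if (type == "final") numeric(0) else out)
  }
  p1 <- .predict_forest(object$stage1, x)
  if (include_train_edges) {
    all_edges <- rbind(object$train_edges, edges[, c("a1", "a2")])
    all_p <- c(object$oof, p1)
  } else {
    all_edges <- edges[, c("a1", "a2")]
    all_p <- p1
  }
  net <- build_network(all_edges, all_p, object$p_clamp)
  tab <- gcp_all(net)
  lut <- stats::setNames(tab$gcp, .edge_key(tab$a1, tab$a2))
  gcp_col <- as.numeric(lut[.edge_key(as.character(edges$a1),
                                      as.character(edges$a2))])
  x2 <- cbind(x, GCP = gcp_col)
  p2 <- .predict_forest(object$stage2, x2)
  if (type == "final") p2 else
    data.frame(stage1 = p1, gcp = gcp_col, final = p2)
}

#' Cross-validated evaluation of the two-stage model
#'
#' Three schemes: `"within_cell"` (random stratified row folds),
#' `"across_chromosome"` (folds are unions of chromosomes, so no
#' chromosome is split between training and testing; the fold count is
#' reduced with a warning when there are fewer chromosomes than folds),
#' and `"across_cell"` (train on all given samples, test on a second
#' sample set passed via `test`). The full two-stage procedure is
#' retrained in every fold and test-fold GCP comes from
#' [predict.two_stage_model()].
#'
#' @param x base feature matrix.
#' @param labels 0/1 vector.
#' @param edges anchor pairs aligned with `x`.
#' @param chrom chromosome per sample (required for
#'   `"across_chromosome"`).
#' @param scheme evaluation scheme.
#' @param k fold count (default 10).
#' @param params [forest_params()].
#' @param seed integer seed.
#' @param test for `"across_cell"`: list with `x`, `labels`, `edges` of
#'   the held-out sample set.
#' @return A `loop_eval` object: `per_fold` data frame (fold, model,
#'   auroc, aupr, accuracy, f1, n_test) over `model` in `{basic, final}`,
#'   and a mean `summary`.
#' @export
cross_validate <- function(x, labels, edges, chrom = NULL,
                           scheme = c("within_cell", "across_chromosome",
                                      "across_cell"),
                           k = 10, params = forest_params(), seed = 1,
                           test = NULL) {
  scheme <- match.arg(scheme)
  rows <- list()
  eval_fold <- function(fold_id, tr, model, det, te_labels) {
    rbind(
      data.frame(fold = fold_id, model = "basic",
                 t(compute_metrics(te_labels, det$stage1)),
                 n_test = length(te_labels)),
      data.frame(fold = fold_id, model = "final",
                 t(compute_metrics(te_labels, det$final)),
                 n_test = length(te_labels))
    )
  }
  if (scheme == "across_cell") {
    if (is.null(test)) stop("across_cell needs a test set", call. = FALSE)
    model <- train_two_stage(x, labels, edges, params, seed)
    det <- stats::predict(model, test$x, test$edges, type = "detail")
    rows[[1]] <- eval_fold(1L, NULL, model, det, test$labels)
    k <- 1L
  } else {
    if (scheme == "across_chromosome") {
      if (is.null(chrom)) stop("across_chromosome needs chrom", call. = FALSE)
      n_chrom <- length(unique(chrom))
      if (n_chrom < k) {
        warning("only ", n_chrom, " chromosomes; reducing folds to ",
                n_chrom)
        k <- n_chrom
      }
      fold <- .fold_assignment(nrow(x), k, seed, groups = chrom)
    } else {
      fold <- .fold_assignment(nrow(x), k, seed, labels = labels)
    }
    for (f in seq_len(k)) {
      te <- fold == f
      model <- train_two_stage(x[!te, , drop = FALSE], labels[!te],
                               edges[!te, , drop = FALSE], params,
                               seed + 1000L * f)
      det <- stats::predict(model, x[te, , drop = FALSE],
                            edges[te, , drop = FALSE], type = "detail")
      rows[[f]] <- eval_fold(f, NULL, model, det, labels[te])
    }
  }
  per_fold <- do.call(rbind, rows)
  rownames(per_fold) <- NULL
  summary <- stats::aggregate(
    per_fold[, c("auroc", "aupr", "accuracy", "f1")],
    by = list(model = per_fold$model), FUN = mean, na.rm = TRUE
  )
  structure(list(per_fold = per_fold, summary = summary, scheme = scheme,
                 k = k), class = "loop_eval")
}

#' @export
print.loop_eval <- function(x, ...) {
  cat("loop_eval (", x$scheme, ", ", x$k, " folds)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Gini feature importances of both stages
#'
#' Impurity (Gini) importances of the basic (stage-one) and final
#' (stage-two) forests, normalized to sum to 1 per model. With
#' `aggregate_motif = TRUE` all one-hot motif-sequence columns are summed
#' into a single `motif_sequence` entry -- ranked individually, the 4-per-
#' base indicator columns would understate the sequence's overall
#' contribution.
#'
#' @param model a `two_stage_model`.
#' @param aggregate_motif collapse one-hot columns into one entry.
#' @return List of data frames `basic` and `final` with columns `feature`,
#'   `importance`, sorted decreasingly.
#' @export
feature_importances <- function(model, aggregate_motif = TRUE) {
  one <- function(fit) {
    imp <- ranger::importance(fit)
    imp <- imp / sum(imp)
    if (aggregate_motif) {
      is_seq <- grepl("(^|_)seq[0-9]+_[ATGC]$", names(imp))
      if (any(is_seq)) {
        imp <- c(imp[!is_seq], motif_sequence = sum(imp[is_seq]))
      }
    }
    df <- data.frame(feature = names(imp), importance = as.numeric(imp),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$importance), ]
    rownames(df) <- NULL
    df
  }
  list(basic = one(model$stage1), final = one(model$stage2))
}

#' Feature-combination ablation
#'
#' Cross-validates the two-stage model on combinations of the three
#' feature groups -- `base` (anchor scalars plus distance), `motif`
#' (one-hot sequence columns) and `inbetween` -- reporting the mean basic
#' and final AUROC per combination.
#'
#' @param x full base feature matrix.
#' @param labels,edges,chrom as in [cross_validate()].
#' @param combos list of character vectors over
#'   `{"base","motif","inbetween"}`; default: all 7 non-empty subsets.
#' @param scheme,k,params,seed passed to [cross_validate()].
#' @return Data frame with `combination`, `basic_auroc`, `final_auroc`.
#' @export
ablation <- function(x, labels, edges, chrom = NULL, combos = NULL,
                     scheme = "within_cell", k = 5,
                     params = forest_params(), seed = 1) {
  groups <- list(
    base = grep("^(L|R)_(strand|score|ctcf_signal|rad21_signal|age)$|^distance$",
                colnames(x), value = TRUE),
    motif = grep("(^|_)seq[0-9]+_[ATGC]$", colnames(x), value = TRUE),
    inbetween = grep("^ib_", colnames(x), value = TRUE)
  )
  if (is.null(combos)) {
    nm <- names(groups)
    combos <- unlist(lapply(seq_along(nm), function(r) {
      asplit(utils::combn(nm, r), 2)
    }), recursive = FALSE)
  }
  res <- lapply(combos, function(cb) {
    cb <- as.character(cb)
    if (length(cb) == 0L || !all(cb %in% names(groups))) {
      stop("invalid feature group combination", call. = FALSE)
    }
    cols <- unlist(groups[cb], use.names = FALSE)
    ev <- cross_validate(x[, cols, drop = FALSE], labels, edges, chrom,
                         scheme = scheme, k = k, params = params,
                         seed = seed)
    data.frame(
      combination = paste(cb, collapse = "+"),
      basic_auroc = ev$summary$auroc[ev$summary$model == "basic"],
      final_auroc = ev$summary$auroc[ev$summary$model == "final"],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
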