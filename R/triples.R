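# Transitive triples, multiway-cluster colocalization and frequency
# profiles. A transitive triple is a tandem loop (A,B) whose two anchors
# are each connected to a shared third anchor C by convergent loops; the
# model is that loop extrusion forms the two convergent loops and spatial
# colocalization at C creates the indirect tandem contact.

#' Find transitive triples in a loop set
#'
#' Enumerates every anchor triple (A, B, C) such that (A, B) is a tandem
#' loop in the set and both (A, C) and (B, C) are bridge loops. Bridges
#' must be convergent by default; `bridge_orientation = "any"` relaxes
#' this. Triples are unique by tandem edge plus third anchor.
#'
#' @param loops sample/loop data frame with columns `a1`, `a2`,
#'   `orientation`.
#' @param bridge_orientation `"convergent"` (default) or `"any"`.
#' @return Data frame with columns `a`, `b` (the tandem pair, canonical
#'   order) and `c` (the shared anchor).
#' @export
find_transitive_triples <- function(loops,
                                    bridge_orientation = c("convergent",
                                                           "any")) {
  bridge_orientation <- match.arg(bridge_orientation)
  empty <- data.frame(a = character(), b = character(), c = character(),
                      stringsAsFactors = FALSE)
  if (nrow(loops) == 0L) return(empty)
  tandem <- loops[loops$orientation == "tandem", , drop = FALSE]
  bridges <- if (bridge_orientation == "convergent") {
    loops[loops$orientation == "convergent", , drop = FALSE]
  } else {
    loops
  }
  if (nrow(tandem) == 0L || nrow(bridges) == 0L) return(empty)
  nb <- split(c(bridges$a2, bridges$a1), c(bridges$a1, bridges$a2))
  out <- vector("list", nrow(tandem))
  for (i in seq_len(nrow(tandem))) {
    a <- tandem$a1[i]; b <- tandem$a2[i]
    common <- setdiff(intersect(nb[[a]], nb[[b]]), c(a, b))
    if (length(common)) {
      out[[i]] <- data.frame(a = min(a, b), b = max(a, b), c = common,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' Assign multiway-cluster members to their nearest anchors
#'
#' Each cluster member is mapped to the nearest anchor/peak on the same
#' chromosome by midpoint distance (ties broken towards the
#' lower-coordinate anchor); members farther than `max_distance` are
#' dropped, and clusters left with fewer than two members are discarded.
#'
#' @param clusters list of interval data frames from
#'   [read_cluster_records()].
#' @param anchors table of reference positions with columns `chrom`,
#'   `start`, `end` and optionally `anchor_id` (row index used otherwise);
#'   typically the valid anchor table or a CTCF peak table.
#' @param max_distance maximum member-to-anchor midpoint distance in bp
#'   (default 5000).
#' @return List of character vectors of anchor ids, one per surviving
#'   cluster.
#' @export
assign_clusters_to_anchors <- function(clusters, anchors,
                                       max_distance = 5000) {
  ids <- if ("anchor_id" %in% names(anchors)) {
    as.character(anchors$anchor_id)
  } else {
    as.character(seq_len(nrow(anchors)))
  }
  amid <- (anchors$start + anchors$end) / 2
  by_chrom <- split(seq_len(nrow(anchors)), anchors$chrom)
  by_chrom <- lapply(by_chrom, function(ix) ix[order(amid[ix])])
  nearest <- function(chrom, mid) {
    ix <- by_chrom[[chrom]]
    if (is.null(ix)) return(NA_integer_)
    mids <- amid[ix]
    pos <- findInterval(mid, mids)
    cand <- unique(pmin(pmax(c(pos, pos + 1L), 1L), length(ix)))
    dd <- abs(mids[cand] - mid)
    best <- cand[order(dd, anchors$start[ix[cand]])][1]
    if (dd[match(best, cand)] > max_distance) NA_integer_ else ix[best]
  }
  out <- lapply(clusters, function(cl) {
    mid <- (cl$start + cl$end) / 2
    hit <- vapply(seq_len(nrow(cl)), function(i) {
      nearest(cl$chrom[i], mid[i])
    }, integer(1))
    ids[hit[!is.na(hit)]]
  })
  out[vapply(out, length, 1L) >= 2L]
}

#' Count cluster support of transitive triples
#'
#' The support of a triple is the number of clusters containing all three
#' of its anchors in one record. Triples reaching `min_count` are marked
#' spatially colocalization-validated.
#'
#' @param triples data frame from [find_transitive_triples()].
#' @param assigned_clusters list of anchor-id vectors from
#'   [assign_clusters_to_anchors()].
#' @param min_count validation threshold (default 20).
#' @return `triples` with added `support_count` and `validated` columns.
#' @export
triple_cluster_support <- function(triples, assigned_clusters,
                                   min_count = 20) {
  member_of <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(assigned_clusters)) {
    for (id in unique(assigned_clusters[[i]])) {
      member_of[[id]] <- c(member_of[[id]], i)
    }
  }
  cl_of <- function(id) {
    v <- member_of[[id]]
    if (is.null(v)) integer(0) else v
  }
  support <- vapply(seq_len(nrow(triples)), function(i) {
    length(Reduce(intersect, list(cl_of(triples$a[i]), cl_of(triples$b[i]),
                                  cl_of(triples$c[i]))))
  }, integer(1))
  triples$support_count <- support
  triples$validated <- support >= min_count
  triples
}

#' Fisher test of tandem-loop colocalization
#'
#' A tandem loop is "valid" when its anchor pair is the tandem edge of a
#' colocalization-validated transitive triple. Builds the 2x2 table of
#' positive/negative tandem loops against valid/non-valid, computes the
#' two-sided Fisher exact p-value and the sample odds ratio (Haldane 0.5
#' correction applied when any cell is zero).
#'
#' @param pos_tandem,neg_tandem sample data frames with `a1`, `a2`.
#' @param validated_triples output of [triple_cluster_support()]; only
#'   rows with `validated == TRUE` count.
#' @return List with `table` (2x2 matrix), `odds_ratio`, `p_value`.
#' @export
colocalization_test <- function(pos_tandem, neg_tandem, validated_triples) {
  if (nrow(pos_tandem) == 0L || nrow(neg_tandem) == 0L) {
    stop("both positive and negative tandem loops are required",
         call. = FALSE)
  }
  vt <- validated_triples[validated_triples$validated, , drop = FALSE]
  vkeys <- unique(.edge_key(vt$a, vt$b))
  is_valid <- function(s) .edge_key(s$a1, s$a2) %in% vkeys
  n11 <- sum(is_valid(pos_tandem)); n12 <- nrow(pos_tandem) - n11
  n21 <- sum(is_valid(neg_tandem)); n22 <- nrow(neg_tandem) - n21
  tab <- matrix(c(n11, n12, n21, n22), nrow = 2, byrow = TRUE,
                dimnames = list(c("positive", "negative"),
                                c("valid", "non_valid")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  if (any(tab == 0)) {
    or <- ((n11 + 0.5) * (n22 + 0.5)) / ((n12 + 0.5) * (n21 + 0.5))
  } else {
    or <- (n11 * n22) / (n12 * n21)
  }
  structure(list(table = tab, odds_ratio = or, p_value = p),
            class = "coloc_test")
}

#' @export
print.coloc_test <- function(x, ...) {
  print(x$table)
  cat("odds ratio:", format(x$odds_ratio),
      " two-sided Fisher p:", format(x$p_value), "\n")
  invisible(x)
}

#' Loop counts by orientation at increasing frequency thresholds
#'
#' For each threshold t, counts the convergent and tandem loops with
#' interaction frequency >= t and the convergent proportion among them.
#' Raising the threshold emulates decreasing sequencing depth; tandem
#' loops, having lower frequencies, drop out faster.
#'
#' @param loops data frame with `orientation` and `frequency`.
#' @param thresholds ascending integer thresholds.
#' @return Data frame with `threshold`, `n_convergent`, `n_tandem`,
#'   `proportion_convergent`.
#' @export
frequency_threshold_profile <- function(loops, thresholds) {
  if (anyNA(loops$frequency) || is.null(loops$frequency)) {
    stop("all loops need a frequency", call. = FALSE)
  }
  res <- lapply(thresholds, function(t) {
    keep <- loops$frequency >= t
    nc <- sum(keep & loops$orientation == "convergent")
    nt <- sum(keep & loops$orientation == "tandem")
    data.frame(threshold = t, n_convergent = nc, n_tandem = nt,
               proportion_convergent = if (nc + nt == 0) NA_real_ else
                 nc / (nc + nt))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
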