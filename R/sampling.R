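# Training-sample generation: valid anchors, positive loops, random
# negatives filtered against observed loops, and distance-decile matching.

# Mutual one-to-one overlap matching between motifs and peaks: keep pairs
# where the motif overlaps exactly one peak AND that peak overlaps exactly
# one motif. Returns a data frame of (motif, peak) row indices.
.mutual_one_to_one <- function(motifs, peaks) {
  if (nrow(motifs) == 0L || nrow(peaks) == 0L) {
    return(data.frame(motif = integer(), peak = integer()))
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(motifs), .as_granges(peaks))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  qdeg <- tabulate(qh, nbins = nrow(motifs))
  sdeg <- tabulate(sh, nbins = nrow(peaks))
  keep <- qdeg[qh] == 1L & sdeg[sh] == 1L
  data.frame(motif = qh[keep], peak = sh[keep])
}

#' Call valid loop anchors from motifs and ChIP-seq peaks
#'
#' A CTCF motif is a valid loop anchor when it is in mutual one-to-one
#' correspondence with a CTCF ChIP-seq peak: the motif overlaps exactly one
#' peak and that peak overlaps exactly one motif. Motifs overlapping two
#' peaks, and pairs of motifs sharing a peak, are excluded. Each anchor
#' carries the matched peak's signal, the maximum signal of any overlapping
#' RAD21 peak (0 when none) and an optional motif-age code.
#'
#' @param motifs motif data frame from [read_motif_occurrences()].
#' @param ctcf_peaks CTCF peak data frame from [read_narrowpeak()].
#' @param rad21_peaks optional RAD21 peak data frame.
#' @param ages optional age table from [read_ages()], joined by exact motif
#'   interval; anchors without a match get age 0.
#' @return Data frame of anchors with columns `anchor_id`, `chrom`, `start`,
#'   `end`, `strand`, `score`, `seq`, `mid`, `ctcf_signal`, `rad21_signal`,
#'   `age`, `peak_start`, `peak_end`, sorted by `(chrom, start)`.
#' @export
call_valid_anchors <- function(motifs, ctcf_peaks, rad21_peaks = NULL,
                               ages = NULL) {
  if (nrow(motifs) == 0L || nrow(ctcf_peaks) == 0L) {
    warning("empty motif or CTCF peak input: no valid anchors")
    return(data.frame(anchor_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      seq = character(), mid = numeric(),
                      ctcf_signal = numeric(), rad21_signal = numeric(),
                      age = numeric(), peak_start = integer(),
                      peak_end = integer(), stringsAsFactors = FALSE))
  }
  mm <- .mutual_one_to_one(motifs, ctcf_peaks)
  m <- motifs[mm$motif, , drop = FALSE]
  pk <- ctcf_peaks[mm$peak, , drop = FALSE]
  out <- data.frame(
    anchor_id = sprintf("%s:%d-%d", m$chrom, m$start, m$end),
    chrom = m$chrom, start = m$start, end = m$end,
    strand = m$strand, score = m$score, seq = m$seq,
    mid = (m$start + m$end) / 2,
    ctcf_signal = pk$signal,
    rad21_signal = 0,
    age = 0,
    peak_start = pk$start, peak_end = pk$end,
    stringsAsFactors = FALSE
  )
  if (!is.null(rad21_peaks) && nrow(rad21_peaks) > 0L) {
    hits <- GenomicRanges::findOverlaps(.as_granges(out),
                                        .as_granges(rad21_peaks))
    if (length(hits)) {
      sig <- tapply(rad21_peaks$signal[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), max)
      out$rad21_signal[as.integer(names(sig))] <- as.numeric(sig)
    }
  }
  if (!is.null(ages) && nrow(ages) > 0L) {
    key <- function(d) paste(d$chrom, d$start, d$end)
    idx <- match(key(out), key(ages))
    out$age[!is.na(idx)] <- ages$age[idx[!is.na(idx)]]
  } else {
    message("call_valid_anchors: no age annotation supplied; ",
            "age feature set to 0")
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the orientation of an anchor pair
#'
#' With the left anchor first, strand pair `(+,-)` is a convergent loop,
#' `(+,+)` and `(-,-)` are tandem loops, and `(-,+)` is divergent.
#'
#' @param strand_l,strand_r strand of the left and right anchor (`"+"` or
#'   `"-"`; vectors recycle).
#' @return Character vector in `{"convergent","tandem","divergent"}`.
#' @export
classify_orientation <- function(strand_l, strand_r) {
  if (any(!strand_l %in% c("+", "-")) || any(!strand_r %in% c("+", "-"))) {
    stop("anchors must be stranded (+ or -)", call. = FALSE)
  }
  code <- paste0(strand_l, strand_r)
  out <- rep("tandem", length(code))
  out[code == "+-"] <- "convergent"
  out[code == "-+"] <- "divergent"
  out
}

#' Extract positive training samples from observed loops
#'
#' A loop becomes a positive sample when each of its two anchor regions
#' overlaps exactly one valid anchor. The sample distance is then
#' recomputed as the separation of the two motif midpoints and must lie
#' strictly inside (10 kb, 1 Mb); loops outside the window or with
#' ambiguous anchor matches are dropped (counts are recorded in the
#' `"n_dropped_ambiguous"` and `"n_dropped_distance"` attributes).
#'
#' @param loops loop data frame from [read_loops_bedpe()].
#' @param anchors valid anchors from [call_valid_anchors()].
#' @param min_distance,max_distance open distance window in bp.
#' @return Sample data frame with columns `chrom`, `a1`, `a2`, `label`,
#'   `orientation`, `distance`, `frequency`.
#' @export
extract_positive_samples <- function(loops, anchors,
                                     min_distance = 1e4,
                                     max_distance = 1e6) {
  empty <- data.frame(chrom = character(), a1 = character(),
                      a2 = character(), label = character(),
                      orientation = character(), distance = numeric(),
                      frequency = integer(), stringsAsFactors = FALSE)
  if (nrow(loops) == 0L || nrow(anchors) == 0L) return(empty)
  ga <- .as_granges(anchors)
  gl <- .as_granges(data.frame(chrom = loops$chrom1, start = loops$start1,
                               end = loops$end1))
  gr <- .as_granges(data.frame(chrom = loops$chrom2, start = loops$start2,
                               end = loops$end2))
  hl <- GenomicRanges::findOverlaps(gl, ga)
  hr <- GenomicRanges::findOverlaps(gr, ga)
  nl <- tabulate(S4Vectors::queryHits(hl), nbins = nrow(loops))
  nr <- tabulate(S4Vectors::queryHits(hr), nbins = nrow(loops))
  ok <- nl == 1L & nr == 1L
  n_ambig <- sum(!ok)
  il <- integer(nrow(loops)); ir <- integer(nrow(loops))
  il[S4Vectors::queryHits(hl)[nl[S4Vectors::queryHits(hl)] == 1L]] <-
    S4Vectors::subjectHits(hl)[nl[S4Vectors::queryHits(hl)] == 1L]
  ir[S4Vectors::queryHits(hr)[nr[S4Vectors::queryHits(hr)] == 1L]] <-
    S4Vectors::subjectHits(hr)[nr[S4Vectors::queryHits(hr)] == 1L]
  keep <- which(ok & il != ir & il > 0L & ir > 0L)
  if (length(keep) == 0L) {
    attr(empty, "n_dropped_ambiguous") <- n_ambig
    attr(empty, "n_dropped_distance") <- 0L
    return(empty)
  }
  aL <- anchors[il[keep], , drop = FALSE]
  aR <- anchors[ir[keep], , drop = FALSE]
  swap <- aL$mid > aR$mid
  if (any(swap)) {
    tmp <- aL[swap, ]; aL[swap, ] <- aR[swap, ]; aR[swap, ] <- tmp
  }
  d <- abs(aR$mid - aL$mid)
  inwin <- d > min_distance & d < max_distance
  out <- data.frame(
    chrom = aL$chrom[inwin],
    a1 = aL$anchor_id[inwin],
    a2 = aR$anchor_id[inwin],
    label = rep("positive", sum(inwin)),
    orientation = classify_orientation(aL$strand[inwin], aR$strand[inwin]),
    distance = d[inwin],
    frequency = loops$frequency[keep][inwin],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_dropped_ambiguous") <- n_ambig
  attr(out, "n_dropped_distance") <- sum(!inwin)
  out
}

# Per-anchor lists of loop indices whose left (right) anchor region the
# anchor motif overlaps; used to reject negative candidates that coincide
# with an observed loop.
.anchor_loop_index <- function(anchors, loops) {
  n <- nrow(anchors)
  left <- vector("list", n); right <- vector("list", n)
  if (nrow(loops) > 0L) {
    ga <- .as_granges(anchors)
    gl <- .as_granges(data.frame(chrom = loops$chrom1, start = loops$start1,
                                 end = loops$end1))
    gr <- .as_granges(data.frame(chrom = loops$chrom2, start = loops$start2,
                                 end = loops$end2))
    hl <- GenomicRanges::findOverlaps(ga, gl)
    hr <- GenomicRanges::findOverlaps(ga, gr)
    left <- unname(split(S4Vectors::subjectHits(hl),
                         factor(S4Vectors::queryHits(hl), levels = seq_len(n))))
    right <- unname(split(S4Vectors::subjectHits(hr),
                          factor(S4Vectors::queryHits(hr), levels = seq_len(n))))
  }
  list(left = left, right = right)
}

#' Generate candidate negative samples by random anchor pairing
#'
#' Draws random same-chromosome pairs of valid anchors of the requested
#' orientation class within the (10 kb, 1 Mb) distance window, discarding
#' pairs whose two anchors both fall inside the two anchor regions of any
#' observed ChIA-PET loop (in either order) as well as duplicate pairs.
#' Sampling is bounded: after `max_factor * n_candidates` draws the
#' candidates found so far are returned with a warning.
#'
#' @param anchors valid anchors from [call_valid_anchors()].
#' @param loops all observed loops (before distance filtering) used for the
#'   overlap rejection.
#' @param orientation `"convergent"`, `"tandem"` or `"divergent"`.
#' @param n_candidates number of candidate pairs requested.
#' @param seed integer seed; equal seeds give identical candidate lists.
#' @param min_distance,max_distance open distance window in bp.
#' @param max_factor bound on total draws, as a multiple of `n_candidates`.
#' @return Sample data frame (`label = "negative"`) as in
#'   [extract_positive_samples()].
#' @export
generate_candidate_negatives <- function(anchors, loops, orientation,
                                         n_candidates, seed,
                                         min_distance = 1e4,
                                         max_distance = 1e6,
                                         max_factor = 100) {
  stopifnot(orientation %in% c("convergent", "tandem", "divergent"),
            n_candidates >= 1)
  set.seed(seed)
  idx <- .anchor_loop_index(anchors, loops)
  by_chrom <- split(seq_len(nrow(anchors)), anchors$chrom)
  by_chrom <- by_chrom[lengths(by_chrom) >= 2L]
  if (length(by_chrom) == 0L) {
    warning("no chromosome with at least two anchors")
    return(.empty_samples())
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  res_a <- integer(0); res_b <- integer(0)
  attempts <- 0L
  max_attempts <- max_factor * n_candidates
  batch <- max(1000L, as.integer(n_candidates))
  while (length(res_a) < n_candidates && attempts < max_attempts) {
    m <- min(batch, max_attempts - attempts)
    attempts <- attempts + m
    ci <- sample(length(by_chrom), m, replace = TRUE,
                 prob = vapply(by_chrom, length, 1L))
    i1 <- integer(m); i2 <- integer(m)
    for (k in seq_len(m)) {
      pair <- sample(by_chrom[[ci[k]]], 2L)
      i1[k] <- pair[1]; i2[k] <- pair[2]
    }
    swap <- anchors$mid[i1] > anchors$mid[i2]
    tmp <- i1[swap]; i1[swap] <- i2[swap]; i2[swap] <- tmp
    d <- anchors$mid[i2] - anchors$mid[i1]
    ok <- d > min_distance & d < max_distance &
      classify_orientation(anchors$strand[i1], anchors$strand[i2]) ==
        orientation
    for (k in which(ok)) {
      a <- i1[k]; b <- i2[k]
      key <- paste0(a, "_", b)
      if (!is.null(seen[[key]])) next
      if (length(intersect(idx$left[[a]], idx$right[[b]])) > 0L ||
          length(intersect(idx$left[[b]], idx$right[[a]])) > 0L) {
        seen[[key]] <- FALSE
        next
      }
      seen[[key]] <- TRUE
      res_a <- c(res_a, a); res_b <- c(res_b, b)
      if (length(res_a) >= n_candidates) break
    }
  }
  if (length(res_a) < n_candidates) {
    warning("found only ", length(res_a), " of ", n_candidates,
            " requested negative candidates after ", attempts, " draws")
  }
  aL <- anchors[res_a, , drop = FALSE]
  aR <- anchors[res_b, , drop = FALSE]
  out <- data.frame(
    chrom = aL$chrom, a1 = aL$anchor_id, a2 = aR$anchor_id,
    label = "negative",
    orientation = rep(orientation, length(res_a)),
    distance = abs(aR$mid - aL$mid),
    frequency = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

.empty_samples <- function() {
  data.frame(chrom = character(), a1 = character(), a2 = character(),
             label = character(), orientation = character(),
             distance = numeric(), frequency = integer(),
             stringsAsFactors = FALSE)
}

#' Distance-matched sampling of negatives
#'
#' Splits the positive samples into `n_bins` equal-count distance bins
#' (stable sort, so tied distances cannot create empty bins), assigns each
#' candidate negative to a bin using the positive bins' distance
#' boundaries, and draws without replacement as many negatives per bin as
#' there are positives in that bin. When a bin holds too few candidates,
#' all available ones are taken and the deficit is reported with a warning.
#'
#' @param positives positive sample data frame.
#' @param candidates candidate negatives from
#'   [generate_candidate_negatives()].
#' @param n_bins number of distance bins (default 10, i.e. deciles).
#' @param seed integer seed.
#' @return The selected negatives; the `"bin_counts"` attribute holds the
#'   per-bin positive/negative counts.
#' @export
distance_matched_sampling <- function(positives, candidates, n_bins = 10,
                                      seed = 1) {
  if (nrow(positives) == 0L) stop("no positive samples", call. = FALSE)
  set.seed(seed)
  n <- nrow(positives)
  n_bins <- max(1L, min(as.integer(n_bins), n))  # no empty positive bins
  ord <- order(positives$distance)  # stable
  bin_of_rank <- ceiling(seq_len(n) * n_bins / n)
  pos_bin <- integer(n)
  pos_bin[ord] <- bin_of_rank
  # internal boundaries: max positive distance in bins 1..n_bins-1
  edges <- vapply(seq_len(n_bins - 1L), function(b) {
    max(positives$distance[pos_bin == b])
  }, numeric(1))
  cand_bin <- findInterval(candidates$distance, edges, left.open = TRUE) + 1L
  picked <- integer(0)
  deficit <- 0L
  counts <- matrix(0L, nrow = n_bins, ncol = 2,
                   dimnames = list(NULL, c("positive", "negative")))
  for (b in seq_len(n_bins)) {
    need <- sum(pos_bin == b)
    avail <- which(cand_bin == b)
    take <- min(need, length(avail))
    if (take < need) deficit <- deficit + (need - take)
    if (take > 0L) picked <- c(picked, sample(avail, take))
    counts[b, ] <- c(need, take)
  }
  if (deficit > 0L) {
    warning("distance_matched_sampling: ", deficit,
            " negative(s) missing due to thin candidate bins")
  }
  out <- candidates[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_counts") <- counts
  out
}

#' Build a balanced training set from raw inputs
#'
#' End-to-end sample generation: valid anchors, positive loops, and
#' distance-matched random negatives produced independently per orientation
#' class (convergent and tandem by default; divergent pairs are excluded
#' from training).
#'
#' @param motifs,ctcf_peaks,rad21_peaks,loops,ages raw inputs as returned
#'   by the `read_*` functions.
#' @param orientations orientation classes to keep.
#' @param n_bins distance bins for matching.
#' @param pool_factor candidate pool size as a multiple of the positive
#'   count, drawn before matching.
#' @param seed integer seed.
#' @return An object of class `loop_dataset`: a list with `anchors`,
#'   `samples`, and the raw `motifs`, `ctcf_peaks`, `rad21_peaks` needed
#'   downstream for feature extraction.
#' @export
prepare_samples <- function(motifs, ctcf_peaks, rad21_peaks, loops,
                            ages = NULL,
                            orientations = c("convergent", "tandem"),
                            n_bins = 10, pool_factor = 10, seed = 1) {
  anchors <- call_valid_anchors(motifs, ctcf_peaks, rad21_peaks, ages)
  positives <- extract_positive_samples(loops, anchors)
  positives <- positives[positives$orientation %in% orientations, ,
                         drop = FALSE]
  pieces <- list()
  for (ori in orientations) {
    pos_o <- positives[positives$orientation == ori, , drop = FALSE]
    if (nrow(pos_o) == 0L) next
    cand <- generate_candidate_negatives(
      anchors, loops, ori,
      n_candidates = pool_factor * nrow(pos_o),
      seed = seed + match(ori, orientations)
    )
    neg_o <- distance_matched_sampling(pos_o, cand, n_bins = n_bins,
                                       seed = seed + 100L +
                                         match(ori, orientations))
    pieces[[ori]] <- rbind(pos_o, neg_o)
  }
  samples <- do.call(rbind, pieces)
  rownames(samples) <- NULL
  structure(
    list(anchors = anchors, samples = samples, motifs = motifs,
         ctcf_peaks = ctcf_peaks, rad21_peaks = rad21_peaks),
    class = "loop_dataset"
  )
}

#' @export
print.loop_dataset <- function(x, ...) {
  cat("loop_dataset:", nrow(x$anchors), "valid anchors,",
      nrow(x$samples), "samples\n")
  if (nrow(x$samples)) {
    print(table(x$samples$orientation, x$samples$label))
  }
  invisible(x)
}
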