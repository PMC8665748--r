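# Per-loop feature construction: anchor scalars, one-hot motif sequence,
# in-between summaries and genomic distance, assembled into a named matrix.

.BASES <- c("A", "T", "G", "C")

.ANCHOR_SCALARS <- c("strand", "score", "ctcf_signal", "rad21_signal", "age")

.IB_NAMES <- c("ib_motif_score_sum", "ib_ctcf_signal_sum",
               "ib_ctcf_signal_plus", "ib_ctcf_signal_minus",
               "ib_motif_count", "ib_motif_count_plus",
               "ib_motif_count_minus", "ib_rad21_count",
               "ib_rad21_signal_sum")

#' One-hot encode a DNA motif sequence
#'
#' Per-base codes are A = `[1,0,0,0]`, T = `[0,1,0,0]`, G = `[0,0,1,0]`,
#' C = `[0,0,0,1]`, concatenated along the sequence, so a length-L motif
#' yields a 4L-long binary vector containing exactly L ones. The encoding
#' is bijective; see [decode_motif_sequence()].
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @param motif_length expected length; defaults to `nchar(seq)`.
#' @return Integer vector of 0/1 of length `4 * motif_length`.
#' @examples
#' encode_motif_sequence("AT")
#' @export
encode_motif_sequence <- function(seq, motif_length = nchar(seq)) {
  if (length(seq) != 1L) stop("encode one sequence at a time", call. = FALSE)
  if (nchar(seq) != motif_length) {
    stop("sequence length ", nchar(seq), " != motif length ", motif_length,
         call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  pos <- match(chars, .BASES)
  if (anyNA(pos)) {
    stop("sequence contains characters outside {A,C,G,T}", call. = FALSE)
  }
  out <- integer(4L * motif_length)
  out[4L * (seq_along(pos) - 1L) + pos] <- 1L
  out
}

#' Decode a one-hot motif vector back to its sequence
#'
#' @param v binary vector of length divisible by 4, one 1 per 4-wide slot.
#' @return The DNA string.
#' @export
decode_motif_sequence <- function(v) {
  if (length(v) %% 4L != 0L) stop("length must be a multiple of 4")
  m <- matrix(v, nrow = 4L)
  if (any(colSums(m) != 1L)) stop("each 4-wide slot must contain one 1")
  paste(.BASES[apply(m, 2L, which.max)], collapse = "")
}

# Batch one-hot encoding; rows = sequences.
.onehot_block <- function(seqs, motif_length) {
  bad <- which(nchar(seqs) != motif_length)
  if (length(bad)) {
    stop("anchor motif length ", nchar(seqs[bad[1]]),
         " does not match schema motif length ", motif_length, call. = FALSE)
  }
  t(vapply(seqs, encode_motif_sequence, integer(4L * motif_length),
           motif_length = motif_length, USE.NAMES = FALSE))
}

.seq_colnames <- function(motif_length) {
  as.vector(t(outer(seq_len(motif_length), .BASES,
                    function(i, b) sprintf("seq%02d_%s", i, b))))
}

#' Define the feature schema
#'
#' Fixes the names, order and width of the per-loop feature vector. The
#' default (`variant = "full"`) layout is: left-anchor block (5 scalars +
#' one-hot motif), right-anchor block, 9 in-between features, distance,
#' and optionally GCP; with a 19-bp motif this is 172 columns (173 with
#' GCP). The `"compat97"` variant keeps one shared motif block (the
#' element-wise OR of the two anchors' encodings) giving 97 columns
#' including GCP.
#'
#' @param motif_length motif width in bp (default 19, the CTCF core motif).
#' @param include_gcp whether the schema ends with a `GCP` column.
#' @param variant `"full"` or `"compat97"`.
#' @return A `feature_schema` object.
#' @export
feature_schema <- function(motif_length = 19, include_gcp = FALSE,
                           variant = c("full", "compat97")) {
  variant <- match.arg(variant)
  sq <- .seq_colnames(motif_length)
  if (variant == "full") {
    nm <- c(paste0("L_", .ANCHOR_SCALARS), paste0("L_", sq),
            paste0("R_", .ANCHOR_SCALARS), paste0("R_", sq),
            .IB_NAMES, "distance")
  } else {
    nm <- c(paste0("L_", .ANCHOR_SCALARS), paste0("R_", .ANCHOR_SCALARS),
            paste0("motif_", sq), .IB_NAMES, "distance")
  }
  if (include_gcp) nm <- c(nm, "GCP")
  stopifnot(!anyDuplicated(nm))
  structure(list(names = nm, motif_length = motif_length,
                 include_gcp = include_gcp, variant = variant,
                 width = length(nm)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("feature_schema (", x$variant, "): ", x$width, " columns, motif ",
      x$motif_length, " bp", if (x$include_gcp) ", with GCP", "\n", sep = "")
  invisible(x)
}

#' Anchor feature vector for a single valid anchor
#'
#' Scalars are strand (plus = 1, minus = 0), motif score, CTCF signal,
#' RAD21 signal and motif age, followed by the one-hot motif sequence.
#'
#' @param anchor one-row anchor data frame.
#' @param motif_length motif width for the one-hot block.
#' @return Named numeric vector of length `5 + 4 * motif_length`.
#' @export
anchor_features <- function(anchor, motif_length = nchar(anchor$seq)) {
  stopifnot(nrow(anchor) == 1L)
  v <- c(as.numeric(anchor$strand == "+"), anchor$score,
         anchor$ctcf_signal, anchor$rad21_signal, anchor$age,
         encode_motif_sequence(anchor$seq, motif_length))
  names(v) <- c(.ANCHOR_SCALARS, .seq_colnames(motif_length))
  v
}

# Scalar + one-hot blocks for a set of anchors (rows align with `rows`).
.anchor_block <- function(anchors, rows, motif_length) {
  a <- anchors[rows, , drop = FALSE]
  scal <- cbind(as.numeric(a$strand == "+"), a$score, a$ctcf_signal,
                a$rad21_signal, a$age)
  colnames(scal) <- .ANCHOR_SCALARS
  oh <- .onehot_block(a$seq, motif_length)
  colnames(oh) <- .seq_colnames(motif_length)
  list(scalars = scal, onehot = oh)
}

#' In-between features for a set of candidate loops
#'
#' Summaries over the open region between the inner edges of the two
#' anchor motifs: sum of in-between CTCF motif scores; sum of CTCF peak
#' signal (total, plus-strand and minus-strand, where a peak inherits a
#' strand from its mutually one-to-one matched motif and contributes only
#' to the unsigned sum otherwise); counts of in-between CTCF motifs
#' (total, plus, minus); and count and summed signal of RAD21 peaks.
#' An element counts as in-between when it lies entirely inside the open
#' region, so the anchors' own motifs and peaks (which protrude into the
#' region) never contaminate the summaries. An empty region yields all
#' zeros.
#'
#' @param samples sample data frame (`chrom`, `a1`, `a2`).
#' @param anchors valid anchor table (defines the motif spans of `a1`/`a2`).
#' @param motifs,ctcf_peaks,rad21_peaks genome-wide inputs.
#' @return Numeric matrix, one row per sample, 9 named columns.
#' @export
inbetween_features <- function(samples, anchors, motifs, ctcf_peaks,
                               rad21_peaks = NULL) {
  n <- nrow(samples)
  out <- matrix(0, nrow = n, ncol = length(.IB_NAMES),
                dimnames = list(NULL, .IB_NAMES))
  if (n == 0L) return(out)
  i1 <- match(samples$a1, anchors$anchor_id)
  i2 <- match(samples$a2, anchors$anchor_id)
  if (anyNA(i1) || anyNA(i2)) stop("sample anchor not in anchor table")
  # inner edges regardless of which anchor is listed first
  rs <- pmin(anchors$end[i1], anchors$end[i2])
  re <- pmax(anchors$start[i1], anchors$start[i2])
  ok <- which(re > rs)
  if (length(ok) == 0L) return(out)
  regions <- data.frame(chrom = samples$chrom[ok], start = rs[ok],
                        end = re[ok])
  greg <- .as_granges(regions)

  add <- function(col, q, values) {
    s <- tapply(values, q, sum)
    out[ok[as.integer(names(s))], col] <<-
      out[ok[as.integer(names(s))], col] + as.numeric(s)
  }
  contained <- function(elements) {
    # hits with the element fully inside the region; returns (region, element)
    h <- GenomicRanges::findOverlaps(.as_granges(elements), greg,
                                     type = "within")
    list(q = S4Vectors::subjectHits(h), s = S4Vectors::queryHits(h))
  }

  if (nrow(motifs) > 0L) {
    hm <- contained(motifs)
    q <- hm$q; s <- hm$s
    if (length(q)) {
      add("ib_motif_score_sum", q, motifs$score[s])
      add("ib_motif_count", q, rep(1, length(s)))
      add("ib_motif_count_plus", q, as.numeric(motifs$strand[s] == "+"))
      add("ib_motif_count_minus", q, as.numeric(motifs$strand[s] == "-"))
    }
  }
  if (nrow(ctcf_peaks) > 0L) {
    peak_strand <- rep(NA_character_, nrow(ctcf_peaks))
    mm <- .mutual_one_to_one(motifs, ctcf_peaks)
    peak_strand[mm$peak] <- motifs$strand[mm$motif]
    hp <- contained(ctcf_peaks)
    q <- hp$q; s <- hp$s
    if (length(q)) {
      add("ib_ctcf_signal_sum", q, ctcf_peaks$signal[s])
      plus <- !is.na(peak_strand[s]) & peak_strand[s] == "+"
      minus <- !is.na(peak_strand[s]) & peak_strand[s] == "-"
      add("ib_ctcf_signal_plus", q, ctcf_peaks$signal[s] * plus)
      add("ib_ctcf_signal_minus", q, ctcf_peaks$signal[s] * minus)
    }
  }
  if (!is.null(rad21_peaks) && nrow(rad21_peaks) > 0L) {
    hr <- contained(rad21_peaks)
    q <- hr$q; s <- hr$s
    if (length(q)) {
      add("ib_rad21_count", q, rep(1, length(s)))
      add("ib_rad21_signal_sum", q, rad21_peaks$signal[s])
    }
  }
  out
}

#' Assemble the per-loop feature matrix
#'
#' Concatenates, per sample, the left- and right-anchor blocks, the
#' in-between block, the anchor-midpoint distance and (when the schema
#' says so) a precomputed GCP column. Row order follows `samples`; column
#' order is fixed by the schema. The construction is deterministic.
#'
#' @param dataset a `loop_dataset` from [prepare_samples()], or a list with
#'   elements `anchors`, `motifs`, `ctcf_peaks`, `rad21_peaks`.
#' @param samples sample data frame; defaults to `dataset$samples`.
#' @param schema a [feature_schema()]; `include_gcp` must agree with
#'   `gcp_values`.
#' @param gcp_values numeric GCP per sample, required iff the schema
#'   includes GCP.
#' @return A `loop_features` object: list with the numeric `x` matrix,
#'   `labels` (1 positive / 0 negative / NA unknown), `schema` and the
#'   `samples` it was built from.
#' @export
assemble_feature_matrix <- function(dataset, samples = dataset$samples,
                                    schema = feature_schema(),
                                    gcp_values = NULL) {
  if (schema$include_gcp && is.null(gcp_values)) {
    stop("schema includes GCP but no gcp_values given", call. = FALSE)
  }
  if (!schema$include_gcp && !is.null(gcp_values)) {
    stop("gcp_values given but schema has no GCP column", call. = FALSE)
  }
  n <- nrow(samples)
  if (!is.null(gcp_values) && length(gcp_values) != n) {
    stop("gcp_values length != sample count", call. = FALSE)
  }
  if (n == 0L) {
    x <- matrix(numeric(0), nrow = 0, ncol = schema$width,
                dimnames = list(NULL, schema$names))
    return(structure(list(x = x, labels = integer(0), schema = schema,
                          samples = samples), class = "loop_features"))
  }
  anchors <- dataset$anchors
  i1 <- match(samples$a1, anchors$anchor_id)
  i2 <- match(samples$a2, anchors$anchor_id)
  if (anyNA(i1) || anyNA(i2)) stop("sample anchor not in anchor table")
  L <- .anchor_block(anchors, i1, schema$motif_length)
  R <- .anchor_block(anchors, i2, schema$motif_length)
  ib <- inbetween_features(samples, anchors, dataset$motifs,
                           dataset$ctcf_peaks, dataset$rad21_peaks)
  if (schema$variant == "full") {
    x <- cbind(L$scalars, L$onehot, R$scalars, R$onehot, ib,
               distance = samples$distance)
  } else {
    x <- cbind(L$scalars, R$scalars, pmax(L$onehot, R$onehot), ib,
               distance = samples$distance)
  }
  if (schema$include_gcp) x <- cbind(x, GCP = gcp_values)
  colnames(x) <- schema$names
  rownames(x) <- NULL
  labels <- ifelse(samples$label == "positive", 1L,
                   ifelse(samples$label == "negative", 0L, NA_integer_))
  structure(list(x = x, labels = labels, schema = schema, samples = samples),
            class = "loop_features")
}

#' @export
print.loop_features <- function(x, ...) {
  cat("loop_features:", nrow(x$x), "samples x", ncol(x$x), "features (",
      x$schema$variant, ")\n")
  invisible(x)
}

#' Write / read a feature matrix as headered TSV
#'
#' The matrix is stored with a trailing `label` column; the schema is
#' saved alongside as a JSON sidecar (`<path>.schema.json`).
#'
#' @param features a `loop_features` object.
#' @param path output TSV path.
#' @export
write_feature_matrix <- function(features, path) {
  df <- as.data.frame(features$x)
  df$label <- features$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(names = features$schema$names,
               motif_length = features$schema$motif_length,
               include_gcp = features$schema$include_gcp,
               variant = features$schema$variant)
  jsonlite::write_json(side, paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @return `read_feature_matrix()` returns a `loop_features` object
#'   (without the `samples` element).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".schema.json"),
                              simplifyVector = TRUE)
  schema <- feature_schema(side$motif_length, side$include_gcp,
                           side$variant)
  labels <- df$label
  x <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  stopifnot(identical(colnames(x), schema$names))
  structure(list(x = x, labels = labels, schema = schema, samples = NULL),
            class = "loop_features")
}
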