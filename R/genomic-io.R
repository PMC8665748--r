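# Readers and writers for the tabular genomic formats the pipeline touches.
# All coordinates are handled internally as 0-based half-open intervals
# (BED convention); readers convert from the source dialect where needed
# and return coordinate-sorted data frames.

#' Convert an interval data frame to a GRanges object
#'
#' Internal bridge between the package's 0-based half-open data frames and
#' the 1-based closed coordinates used by [GenomicRanges::GRanges].
#'
#' @param df data frame with columns `chrom`, `start`, `end`.
#' @return A `GRanges` with one range per row.
#' @keywords internal
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.open_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gzfile(path)  # reads plain text transparently as well
}

.check_intervals <- function(df, what) {
  bad <- which(df$start < 0 | df$end <= df$start | !nzchar(df$chrom))
  if (length(bad)) {
    stop("invalid ", what, " interval(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": need start >= 0, end > start, non-empty chrom", call. = FALSE)
  }
  invisible(df)
}

#' Read CTCF motif occurrences from a motif-scanner table
#'
#' Parses the tab-separated output of a PWM motif scanner (FIMO-style) with
#' a header naming at least the columns `chrom`, `start`, `stop`, `strand`,
#' `score` and `matched_sequence`. Scanner coordinates are 1-based inclusive
#' and are converted to the package's 0-based half-open convention.
#'
#' @param path path to the (optionally gzip-compressed) table.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `score`, `seq`, sorted by `(chrom, start)`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tstart\tstop\tstrand\tscore\tmatched_sequence",
#'              "chr1\t1001\t1019\t+\t18.3\tTTGCAGTGGCCACCAGGTG"), tf)
#' read_motif_occurrences(tf)
#' @export
read_motif_occurrences <- function(path) {
  con <- .open_text(path)
  raw <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("chrom", "start", "stop", "strand", "score", "matched_sequence")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("motif table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  start1 <- suppressWarnings(as.integer(raw$start))
  stop1 <- suppressWarnings(as.integer(raw$stop))
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(start1) | is.na(stop1) | is.na(score) |
                 !raw$strand %in% c("+", "-"))
  if (length(bad)) {
    stop("malformed motif row at line ", bad[1] + 1L,
         " (counting the header as line 1)", call. = FALSE)
  }
  out <- data.frame(
    chrom = as.character(raw$chrom),
    start = start1 - 1L,     # 1-based inclusive -> 0-based half-open
    end = stop1,
    strand = as.character(raw$strand),
    score = score,
    seq = toupper(as.character(raw$matched_sequence)),
    stringsAsFactors = FALSE
  )
  lenbad <- which(nchar(out$seq) != out$end - out$start)
  if (length(lenbad)) {
    stop("matched sequence length disagrees with interval span at line ",
         lenbad[1] + 1L, call. = FALSE)
  }
  if (any(grepl("[^ACGT]", out$seq))) {
    stop("matched sequence contains characters outside {A,C,G,T}",
         call. = FALSE)
  }
  .check_intervals(out, "motif")
  .sort_intervals(out)
}

#' Read ChIP-seq binding peaks from a narrowPeak file
#'
#' Standard ENCODE narrowPeak (BED6+4, 10 columns, no header). The
#' enrichment signal is taken from column 7 (`signalValue`). Overlapping
#' peaks are retained as-is; no merging is performed.
#'
#' @param path path to the narrowPeak file (optionally gzipped).
#' @return Data frame with columns `chrom`, `start`, `end`, `signal`,
#'   sorted by `(chrom, start)`.
#' @export
read_narrowpeak <- function(path) {
  con <- .open_text(path)
  raw <- utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      signal = numeric(), stringsAsFactors = FALSE))
  }
  if (ncol(raw) != 10L) {
    stop("narrowPeak file must have exactly 10 columns, found ", ncol(raw),
         call. = FALSE)
  }
  out <- data.frame(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    signal = as.numeric(raw[[7]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end) || anyNA(out$signal)) {
    stop("malformed narrowPeak row", call. = FALSE)
  }
  if (any(out$signal < 0)) {
    stop("negative signalValue in narrowPeak file", call. = FALSE)
  }
  .check_intervals(out, "peak")
  .sort_intervals(out)
}

#' Read chromatin loops from a BEDPE file
#'
#' Accepts 6 or more tab-separated columns without a header; column 7 is an
#' optional name and column 8, when present and not `"."`, is read as the
#' PET/interaction frequency of the loop. Records are canonicalized so that
#' the left anchor precedes the right anchor. Inter-chromosomal records are
#' excluded (only intra-chromosomal loops are analysed); their count is
#' reported via a message and the `"n_interchrom"` attribute.
#'
#' @param path path to the BEDPE file (optionally gzipped).
#' @return Data frame with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `frequency` (NA when absent), sorted by
#'   `(chrom1, start1, start2)`.
#' @seealso [write_loops_bedpe()]
#' @export
read_loops_bedpe <- function(path) {
  con <- .open_text(path)
  raw <- utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE)
  empty <- data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      frequency = integer(), stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    attr(empty, "n_interchrom") <- 0L
    return(empty)
  }
  if (ncol(raw) < 6L) {
    stop("BEDPE file must have at least 6 columns, found ", ncol(raw),
         call. = FALSE)
  }
  freq <- rep(NA_integer_, nrow(raw))
  if (ncol(raw) >= 8L) {
    fr <- as.character(raw[[8]])
    has <- fr != "." & !is.na(fr)
    freq[has] <- as.integer(fr[has])
    if (any(!is.na(freq) & freq < 1L)) {
      stop("loop frequency must be a positive integer", call. = FALSE)
    }
  }
  out <- data.frame(
    chrom1 = as.character(raw[[1]]), start1 = as.integer(raw[[2]]),
    end1 = as.integer(raw[[3]]),
    chrom2 = as.character(raw[[4]]), start2 = as.integer(raw[[5]]),
    end2 = as.integer(raw[[6]]),
    frequency = freq, stringsAsFactors = FALSE
  )
  inter <- out$chrom1 != out$chrom2
  n_inter <- sum(inter)
  if (n_inter > 0L) {
    message("read_loops_bedpe: dropped ", n_inter,
            " inter-chromosomal record(s)")
    out <- out[!inter, , drop = FALSE]
  }
  # canonical order: left anchor first
  swap <- out$start1 > out$start2
  if (any(swap)) {
    tmp <- out[swap, c("start2", "end2")]
    out[swap, c("start2", "end2")] <- out[swap, c("start1", "end1")]
    out[swap, c("start1", "end1")] <- tmp
  }
  out <- out[order(out$chrom1, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_interchrom") <- n_inter
  out
}

#' Write chromatin loops to a BEDPE file
#'
#' Emits 8 tab-separated columns (both anchors, a `.` name placeholder and
#' the frequency, `.` when missing). Reading the file back with
#' [read_loops_bedpe()] reproduces the input on canonical records.
#'
#' @param loops data frame as returned by [read_loops_bedpe()].
#' @param path output path.
#' @export
write_loops_bedpe <- function(loops, path) {
  freq <- loops$frequency
  if (is.null(freq)) freq <- rep(NA_integer_, nrow(loops))
  tab <- data.frame(
    loops$chrom1, loops$start1, loops$end1,
    loops$chrom2, loops$start2, loops$end2,
    ".", ifelse(is.na(freq), ".", as.character(freq)),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read multiway contact cluster records
#'
#' One cluster per line, each a whitespace-separated list of
#' `chrom:start-end` intervals (0-based half-open). Clusters are sets of
#' genomic regions captured in the same multiway spatial contact complex
#' (e.g. SPRITE clusters); each must contain at least two members.
#'
#' @param path path to the cluster file (optionally gzipped).
#' @return A list of data frames, each with columns `chrom`, `start`, `end`.
#' @export
read_cluster_records <- function(path) {
  con <- .open_text(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[nzchar(trimws(lines))]
  parse_line <- function(i) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) < 2L) {
      stop("cluster at line ", i, " has fewer than 2 members", call. = FALSE)
    }
    m <- regmatches(toks, regexec("^(.+):([0-9]+)-([0-9]+)$", toks))
    if (any(lengths(m) != 4L)) {
      stop("malformed cluster member at line ", i, call. = FALSE)
    }
    df <- data.frame(
      chrom = vapply(m, `[`, "", 2L),
      start = as.integer(vapply(m, `[`, "", 3L)),
      end = as.integer(vapply(m, `[`, "", 4L)),
      stringsAsFactors = FALSE
    )
    .check_intervals(df, "cluster member")
  }
  lapply(seq_along(lines), parse_line)
}

#' Write multiway contact cluster records
#'
#' Inverse of [read_cluster_records()].
#'
#' @param clusters list of interval data frames.
#' @param path output path.
#' @export
write_cluster_records <- function(clusters, path) {
  lines <- vapply(clusters, function(df) {
    paste(sprintf("%s:%d-%d", df$chrom, df$start, df$end), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read chromatin-state annotations from a 4-column BED file
#'
#' Columns: chrom, start, end, state label (e.g. `promoter`, `enhancer`).
#'
#' @param path path to the BED file (optionally gzipped).
#' @return Data frame with columns `chrom`, `start`, `end`, `state`, sorted.
#' @export
read_state_bed <- function(path) {
  con <- .open_text(path)
  raw <- utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      state = character(), stringsAsFactors = FALSE))
  }
  if (ncol(raw) < 4L) stop("state BED needs 4 columns", call. = FALSE)
  out <- data.frame(
    chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]), state = as.character(raw[[4]]),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$state))) stop("empty state label", call. = FALSE)
  .check_intervals(out, "state")
  .sort_intervals(out)
}

#' Read motif-age annotations
#'
#' Tab-separated table with header columns `chrom`, `start`, `end`, `age`
#' giving a categorical/ordinal evolutionary-age code (branch of origin)
#' per motif interval, 0-based half-open coordinates.
#'
#' @param path path to the table (optionally gzipped).
#' @return Data frame with columns `chrom`, `start`, `end`, `age`.
#' @export
read_ages <- function(path) {
  con <- .open_text(path)
  raw <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "age")
  if (!all(need %in% names(raw))) {
    stop("age table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, need]
  out$age <- as.numeric(out$age)
  .sort_intervals(out)
}

#' Test whether two intervals overlap
#'
#' Overlap means sharing at least one base on the same chromosome
#' (0-based half-open coordinates). Vectorized and symmetric in its two
#' interval arguments.
#'
#' @param chrom1,start1,end1 first interval (vectors recycle).
#' @param chrom2,start2,end2 second interval.
#' @return Logical vector.
#' @export
intervals_overlap <- function(chrom1, start1, end1, chrom2, start2, end2) {
  chrom1 == chrom2 & pmax(start1, start2) < pmin(end1, end2)
}
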