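# Small programmatic fixtures shared across test files.

# A compact synthetic genome: dense enough for loops and triples to form,
# small enough that every test stays fast.
small_sim_config <- function(...) {
  simulation_config(n_chromosomes = 2L, n_anchors = 80L,
                    chromosome_length = 4e6, n_background_clusters = 50L,
                    ...)
}

# Landscape + loops + prepared samples for the small genome, built once
# per test file via a memo environment keyed by seed.
.fixture_memo <- new.env(parent = emptyenv())

small_prepared <- function(seed = 42) {
  key <- paste0("prep", seed)
  if (is.null(.fixture_memo[[key]])) {
    cfg <- small_sim_config()
    land <- simulate_anchor_landscape(cfg, seed)
    sim <- simulate_loops(land, cfg, seed + 1L)
    prep <- suppressWarnings(
      prepare_samples(land$motifs, land$ctcf_peaks, land$rad21_peaks,
                      sim$loops, land$ages, seed = seed + 2L)
    )
    .fixture_memo[[key]] <- list(cfg = cfg, land = land, sim = sim,
                                 prep = prep)
  }
  .fixture_memo[[key]]
}

# Hand-made motif / peak / loop tables for precise matching tests.
mk_motifs <- function(start, strand = "+", chrom = "chr1", score = 10,
                      len = 19) {
  n <- length(start)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len),
             strand = rep_len(strand, n), score = rep_len(score, n),
             seq = vapply(seq_len(n), function(i) {
               paste(rep("A", len), collapse = "")
             }, character(1)),
             stringsAsFactors = FALSE)
}

mk_peaks <- function(start, end, signal = 5, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             signal = rep_len(signal, length(start)),
             stringsAsFactors = FALSE)
}

mk_loops <- function(s1, e1, s2, e2, chrom = "chr1", frequency = NA) {
  data.frame(chrom1 = chrom, start1 = as.integer(s1), end1 = as.integer(e1),
             chrom2 = chrom, start2 = as.integer(s2), end2 = as.integer(e2),
             frequency = as.integer(rep_len(frequency, length(s1))),
             stringsAsFactors = FALSE)
}

# Feature matrix + labels where a single column separates the classes
# perfectly; anchors laid out so each sample is its own disjoint edge.
separable_fixture <- function(n = 60, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), n / 2)
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[, 1] <- labels * 10 + rnorm(n, sd = 0.1)
  edges <- data.frame(a1 = sprintf("L%03d", seq_len(n)),
                      a2 = sprintf("R%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
  list(x = x, labels = labels, edges = edges)
}
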