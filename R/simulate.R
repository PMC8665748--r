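# Synthetic data generator. Emulates the generative story behind
# CTCF-loop training data: stranded scored motifs backed one-to-one by
# CTCF peaks (plus decoys that violate the matching), direct convergent
# loops formed with distance decay by loop extrusion, indirect tandem
# loops closed transitively through a shared anchor, low-level noise
# loops, PET frequencies that are higher for direct than for transitive
# loops, and multiway contact clusters concentrated on transitive
# triples. Everything is reproducible from a single integer seed.

#' Simulation configuration
#'
#' Returns the default synthetic-genome configuration; any field can be
#' overridden by name. Defaults describe four 12-Mb chromosomes with 300
#' anchors each (>= 20 kb apart), a 19-bp motif, log-normal ChIP signals
#' whose log-mean shifts with a latent per-anchor loop propensity
#' (`signal_coupling`), distance-decayed direct convergent loops, a 0.6
#' probability of transitively closing each closeable tandem pair, and
#' Poisson PET frequencies with direct loops drawing higher counts than
#' transitive ones. With the default seed this yields a training set of
#' roughly a thousand positive loops.
#'
#' @param ... named overrides of the default fields.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_chromosomes = 4L,
    chromosome_length = 12e6,
    n_anchors = 300L,          # per chromosome
    motif_length = 19L,
    strand_prob = 0.5,
    min_spacing = 2e4,
    decoy_fraction = 0.1,
    rad21_prob = 0.9,
    propensity_intercept = 1,
    signal_coupling = 0.4,     # log-mean shift of signals per unit propensity
    motif_score_mean = 15,
    motif_score_sd = 2,
    ctcf_signal_meanlog = log(20),
    rad21_signal_meanlog = log(15),
    signal_sdlog = 0.5,
    decay_scale = 2.5e5,       # bp; exp(-d/scale) distance decay
    p_direct_convergent = 0.75,
    transitivity_rate = 0.6,
    noise_rate = 0.05,
    direct_freq_mean = 20,
    transitive_freq_mean = 4,
    noise_freq_mean = 2,
    freq_offset = 2L,
    clusters_per_triple = 30,
    n_background_clusters = 300L,
    cluster_jitter = 2000,
    cluster_halfwidth = 500,
    min_distance = 1e4,
    max_distance = 1e6
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown simulation option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  probs <- c(cfg$strand_prob, cfg$decoy_fraction, cfg$rad21_prob,
             cfg$p_direct_convergent, cfg$transitivity_rate, cfg$noise_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$chromosome_length <= 0 || cfg$motif_length <= 0) {
    stop("lengths must be positive", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

.random_seqs <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Simulate the anchor landscape
#'
#' Places anchors uniformly along each chromosome with a guaranteed
#' minimum spacing, gives each a stranded scored motif backed by exactly
#' one CTCF peak (and, with probability `rad21_prob`, one RAD21 peak),
#' draws log-normal signal values whose log-mean shifts with the anchor's
#' latent loop propensity, and adds decoy motifs/peaks that violate the
#' one-to-one matching (motifs under two peaks and peak spans covering
#' two motifs) to exercise the anchor-calling filter.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return An `anchor_landscape` list: `motifs`, `ctcf_peaks`,
#'   `rad21_peaks`, `ages` (readable tables as produced by the `read_*`
#'   functions) and `truth` (the non-decoy anchors with their latent
#'   propensity `z` and matched peak span).
#' @export
simulate_anchor_landscape <- function(config = simulation_config(),
                                      seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_anchors <= 0) stop("n_anchors must be positive", call. = FALSE)
  set.seed(seed)
  n <- config$n_anchors
  L <- config$chromosome_length
  ml <- config$motif_length
  slack <- L - (n + 1) * config$min_spacing
  if (slack <= 0) {
    stop("infeasible spacing: n_anchors * min_spacing exceeds chromosome",
         call. = FALSE)
  }
  motifs <- list(); cpeaks <- list(); rpeaks <- list(); truth <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    u <- sort(stats::runif(n, 0, slack))
    pos <- as.integer(round(config$min_spacing + u +
                              (seq_len(n) - 1) * config$min_spacing))
    strand <- ifelse(stats::rbinom(n, 1, config$strand_prob) == 1, "+", "-")
    z <- stats::rnorm(n)
    score <- stats::rnorm(n, config$motif_score_mean, config$motif_score_sd)
    seqs <- .random_seqs(n, ml)
    extl <- sample(50:200, n, replace = TRUE)
    extr <- sample(50:200, n, replace = TRUE)
    ctcf_sig <- stats::rlnorm(n, config$ctcf_signal_meanlog +
                                config$signal_coupling * z,
                              config$signal_sdlog)
    has_rad <- stats::rbinom(n, 1, config$rad21_prob) == 1
    rad_sig <- stats::rlnorm(n, config$rad21_signal_meanlog +
                               config$signal_coupling * z,
                             config$signal_sdlog)
    motifs[[chrom]] <- data.frame(
      chrom = chrom, start = pos, end = pos + ml, strand = strand,
      score = round(score, 3), seq = seqs, stringsAsFactors = FALSE
    )
    cpeaks[[chrom]] <- data.frame(
      chrom = chrom, start = pos - extl, end = pos + ml + extr,
      signal = round(ctcf_sig, 3), stringsAsFactors = FALSE
    )
    rpeaks[[chrom]] <- data.frame(
      chrom = chrom, start = (pos - extl)[has_rad],
      end = (pos + ml + extr)[has_rad],
      signal = round(rad_sig, 3)[has_rad], stringsAsFactors = FALSE
    )
    truth[[chrom]] <- data.frame(
      chrom = chrom, start = pos, end = pos + ml, strand = strand,
      mid = pos + ml / 2, z = z,
      anchor_id = sprintf("%s:%d-%d", chrom, pos, pos + ml),
      peak_start = pos - extl, peak_end = pos + ml + extr,
      stringsAsFactors = FALSE
    )
    # decoys in the inter-anchor gaps, >= 5 kb away from any real anchor
    nd <- round(config$decoy_fraction * n)
    if (nd > 0) {
      gap_mid <- as.integer(round((pos[-n] + pos[-1]) / 2))
      gap_mid <- gap_mid[sample.int(length(gap_mid), min(nd,
                                                         length(gap_mid)))]
      half <- length(gap_mid) %/% 2
      dm <- list(); dp <- list()
      if (half > 0) {
        # type A: one motif under two CTCF peaks
        gm <- gap_mid[seq_len(half)]
        dm[[1]] <- data.frame(chrom = chrom, start = gm, end = gm + ml,
                              strand = "+",
                              score = round(stats::rnorm(half,
                                config$motif_score_mean,
                                config$motif_score_sd), 3),
                              seq = .random_seqs(half, ml),
                              stringsAsFactors = FALSE)
        dp[[1]] <- data.frame(chrom = rep(chrom, 2 * half),
                              start = c(gm - 150, gm + 5),
                              end = c(gm + 10, gm + ml + 150),
                              signal = round(stats::rlnorm(2 * half,
                                config$ctcf_signal_meanlog,
                                config$signal_sdlog), 3),
                              stringsAsFactors = FALSE)
      }
      rest <- gap_mid[-seq_len(half)]
      if (length(rest) > 0) {
        # type B: two motifs covered by one peak
        dm[[2]] <- data.frame(chrom = rep(chrom, 2 * length(rest)),
                              start = c(rest, rest + ml + 50),
                              end = c(rest + ml, rest + 2 * ml + 50),
                              strand = rep(c("+", "-"), each = length(rest)),
                              score = round(stats::rnorm(2 * length(rest),
                                config$motif_score_mean,
                                config$motif_score_sd), 3),
                              seq = .random_seqs(2 * length(rest), ml),
                              stringsAsFactors = FALSE)
        dp[[2]] <- data.frame(chrom = chrom, start = rest - 100,
                              end = rest + 2 * ml + 150,
                              signal = round(stats::rlnorm(length(rest),
                                config$ctcf_signal_meanlog,
                                config$signal_sdlog), 3),
                              stringsAsFactors = FALSE)
      }
      motifs[[chrom]] <- rbind(motifs[[chrom]], do.call(rbind, dm))
      cpeaks[[chrom]] <- rbind(cpeaks[[chrom]], do.call(rbind, dp))
    }
  }
  as_int <- function(df) {
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    df
  }
  motifs <- .sort_intervals(as_int(do.call(rbind, motifs)))
  cpeaks <- .sort_intervals(as_int(do.call(rbind, cpeaks)))
  rpeaks <- .sort_intervals(as_int(do.call(rbind, rpeaks)))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  ages <- data.frame(chrom = motifs$chrom, start = motifs$start,
                     end = motifs$end,
                     age = sample(0:8, nrow(motifs), replace = TRUE),
                     stringsAsFactors = FALSE)
  structure(list(motifs = motifs, ctcf_peaks = cpeaks,
                 rad21_peaks = rpeaks, ages = ages, truth = truth),
            class = "anchor_landscape")
}

#' Simulate loops from an anchor landscape
#'
#' Direct loops: every convergent anchor pair within the distance window
#' is accepted with probability
#' `p_direct_convergent * exp(-d / decay_scale) * q_a * q_b`, where
#' `q = plogis(propensity_intercept + z)` couples acceptance to the
#' latent anchor propensity that also shifts the ChIP signals.
#' Transitive loops: for each pair of direct loops sharing an anchor, the
#' closing pair (necessarily tandem, both partners sitting on the same
#' side of the shared anchor) becomes a loop with probability
#' `transitivity_rate` when its distance is in the window; the shared
#' anchor is recorded as the mediator. Noise loops are random non-loop
#' in-window pairs of any orientation, `noise_rate` per true loop. PET
#' frequencies are `freq_offset + Poisson(mean)` with mechanism-specific
#' means (direct > transitive > noise).
#'
#' @param landscape an `anchor_landscape`.
#' @param config the same [simulation_config()].
#' @param seed integer seed.
#' @return A `simulated_loops` list: `loops` (BEDPE-style data frame whose
#'   anchor intervals are the matched CTCF peak spans, with `frequency`)
#'   and `truth` (per loop: anchor ids, `orientation`, `distance`,
#'   `mechanism` in direct/transitive/noise, `mediator` anchor for
#'   transitive loops, `frequency`).
#' @export
simulate_loops <- function(landscape, config = simulation_config(),
                           seed = 1) {
  A <- landscape$truth
  if (is.null(A) || nrow(A) == 0L) stop("no anchors", call. = FALSE)
  set.seed(seed)
  q <- stats::plogis(config$propensity_intercept + A$z)
  pairs <- list()
  for (chrom in unique(A$chrom)) {
    ix <- which(A$chrom == chrom)
    mids <- A$mid[ix]
    dd <- outer(mids, mids, function(a, b) b - a)
    sel <- which(dd > config$min_distance & dd < config$max_distance,
                 arr.ind = TRUE)
    if (nrow(sel) == 0L) next
    i <- ix[sel[, 1]]; j <- ix[sel[, 2]]     # i left of j
    conv <- A$strand[i] == "+" & A$strand[j] == "-"
    i <- i[conv]; j <- j[conv]
    if (length(i) == 0L) next
    d <- A$mid[j] - A$mid[i]
    acc <- config$p_direct_convergent * exp(-d / config$decay_scale) *
      q[i] * q[j]
    take <- stats::runif(length(i)) < acc
    pairs[[chrom]] <- cbind(i[take], j[take])
  }
  direct <- do.call(rbind, pairs)
  if (is.null(direct)) direct <- matrix(integer(0), ncol = 2)
  # transitive closures through shared anchors
  trans <- matrix(integer(0), ncol = 3)   # (i, j, mediator)
  if (nrow(direct) > 1L) {
    nbr <- split(c(direct[, 2], direct[, 1]), c(direct[, 1], direct[, 2]))
    closed <- new.env(hash = TRUE, parent = emptyenv())
    rows <- list()
    for (cs in names(nbr)) {
      partners <- sort(unique(nbr[[cs]]))
      if (length(partners) < 2L) next
      cb <- utils::combn(partners, 2L)
      for (kk in seq_len(ncol(cb))) {
        a <- cb[1, kk]; b <- cb[2, kk]
        d <- abs(A$mid[b] - A$mid[a])
        if (d <= config$min_distance || d >= config$max_distance) next
        key <- paste0(a, "_", b)
        if (!is.null(closed[[key]])) next
        closed[[key]] <- TRUE
        if (stats::runif(1) < config$transitivity_rate) {
          rows[[length(rows) + 1L]] <- c(a, b, as.integer(cs))
        }
      }
    }
    if (length(rows)) trans <- do.call(rbind, rows)
  }
  n_true <- nrow(direct) + nrow(trans)
  if (n_true == 0L) stop("no loops generated; check config", call. = FALSE)
  # noise: random non-loop pairs within the window, any orientation
  loop_keys <- new.env(hash = TRUE, parent = emptyenv())
  mark <- function(a, b) loop_keys[[paste0(min(a, b), "_", max(a, b))]] <- TRUE
  known <- function(a, b) !is.null(loop_keys[[paste0(min(a, b), "_",
                                                     max(a, b))]])
  for (r in seq_len(nrow(direct))) mark(direct[r, 1], direct[r, 2])
  for (r in seq_len(nrow(trans))) mark(trans[r, 1], trans[r, 2])
  n_noise <- round(config$noise_rate * n_true)
  noise <- matrix(integer(0), ncol = 2)
  if (n_noise > 0) {
    got <- 0L; tries <- 0L; acc <- list()
    while (got < n_noise && tries < 100L * n_noise) {
      tries <- tries + 1L
      a <- sample.int(nrow(A), 1L)
      cand <- which(A$chrom == A$chrom[a] &
                      abs(A$mid - A$mid[a]) > config$min_distance &
                      abs(A$mid - A$mid[a]) < config$max_distance)
      if (!length(cand)) next
      b <- cand[sample.int(length(cand), 1L)]
      lo <- min(a, b); hi <- max(a, b)
      if (known(lo, hi)) next
      mark(lo, hi)
      got <- got + 1L
      acc[[got]] <- c(lo, hi)
    }
    if (got > 0) noise <- do.call(rbind, acc)
  }
  mech <- c(rep("direct", nrow(direct)), rep("transitive", nrow(trans)),
            rep("noise", nrow(noise)))
  ii <- c(direct[, 1], trans[, 1], noise[, 1])
  jj <- c(direct[, 2], trans[, 2], noise[, 2])
  mediator <- c(rep(NA_integer_, nrow(direct)), trans[, 3],
                rep(NA_integer_, nrow(noise)))
  lambda <- c(direct = config$direct_freq_mean,
              transitive = config$transitive_freq_mean,
              noise = config$noise_freq_mean)[mech]
  freq <- config$freq_offset + stats::rpois(length(ii), lambda)
  truth <- data.frame(
    chrom = A$chrom[ii],
    a1 = A$anchor_id[ii], a2 = A$anchor_id[jj],
    orientation = classify_orientation(A$strand[ii], A$strand[jj]),
    distance = abs(A$mid[jj] - A$mid[ii]),
    mechanism = mech,
    mediator = ifelse(is.na(mediator), NA_character_,
                      A$anchor_id[mediator]),
    frequency = freq,
    stringsAsFactors = FALSE
  )
  loops <- data.frame(
    chrom1 = A$chrom[ii], start1 = A$peak_start[ii], end1 = A$peak_end[ii],
    chrom2 = A$chrom[jj], start2 = A$peak_start[jj], end2 = A$peak_end[jj],
    frequency = freq, stringsAsFactors = FALSE
  )
  ord <- order(loops$chrom1, loops$start1, loops$start2)
  loops <- loops[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(loops) <- rownames(truth) <- NULL
  structure(list(loops = loops, truth = truth), class = "simulated_loops")
}

#' Simulate multiway contact clusters
#'
#' Every transitive triple (the two tandem anchors plus the mediator)
#' emits `Poisson(clusters_per_triple)` clusters whose three member
#' intervals sit on the triple's anchors with positional jitter bounded
#' by `cluster_jitter` (2 kb by default, safely inside the 5-kb
#' assignment rule). Background clusters sample random anchor sets of
#' size 2-5.
#'
#' @param sim a `simulated_loops` object.
#' @param landscape the `anchor_landscape` the loops came from.
#' @param config the same [simulation_config()].
#' @param seed integer seed.
#' @return List of cluster data frames (columns `chrom`, `start`, `end`).
#' @export
simulate_clusters <- function(sim, landscape,
                              config = simulation_config(), seed = 1) {
  set.seed(seed)
  A <- landscape$truth
  member <- function(row) {
    jit <- round(stats::runif(1, -config$cluster_jitter,
                              config$cluster_jitter))
    data.frame(chrom = A$chrom[row],
               start = as.integer(round(A$mid[row] -
                                          config$cluster_halfwidth + jit)),
               end = as.integer(round(A$mid[row] +
                                        config$cluster_halfwidth + jit)),
               stringsAsFactors = FALSE)
  }
  clusters <- list()
  tr <- sim$truth[sim$truth$mechanism == "transitive", , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    rows <- match(c(tr$a1[i], tr$a2[i], tr$mediator[i]), A$anchor_id)
    for (k in seq_len(stats::rpois(1, config$clusters_per_triple))) {
      clusters[[length(clusters) + 1L]] <-
        do.call(rbind, lapply(rows, member))
    }
  }
  for (k in seq_len(config$n_background_clusters)) {
    rows <- sample.int(nrow(A), sample(2:5, 1))
    clusters[[length(clusters) + 1L]] <- do.call(rbind, lapply(rows, member))
  }
  clusters
}

#' Generate and write a complete synthetic dataset bundle
#'
#' Runs the landscape, loop and cluster generators and writes the file
#' bundle in the formats the readers expect: `motifs.tsv` (scanner-style,
#' 1-based inclusive), `ctcf.narrowPeak`, `rad21.narrowPeak`,
#' `loops.bedpe` (with frequency), `clusters.txt`, `ages.tsv`,
#' `truth.tsv` and a `manifest.json` recording the configuration and
#' seed. Equal seeds and configurations give byte-identical bundles.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`landscape`,
#'   `sim`, `clusters`) and the file `paths`.
#' @export
make_dataset <- function(config = simulation_config(), seed = 1,
                         outdir) {
  landscape <- simulate_anchor_landscape(config, seed)
  sim <- simulate_loops(landscape, config, seed + 1L)
  clusters <- simulate_clusters(sim, landscape, config, seed + 2L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    motifs = file.path(outdir, "motifs.tsv"),
    ctcf = file.path(outdir, "ctcf.narrowPeak"),
    rad21 = file.path(outdir, "rad21.narrowPeak"),
    loops = file.path(outdir, "loops.bedpe"),
    clusters = file.path(outdir, "clusters.txt"),
    ages = file.path(outdir, "ages.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
  m <- landscape$motifs
  mt <- data.frame(chrom = m$chrom, start = m$start + 1L, stop = m$end,
                   strand = m$strand, score = m$score,
                   matched_sequence = m$seq, stringsAsFactors = FALSE)
  utils::write.table(mt, paths$motifs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  np <- function(df, path) {
    tab <- data.frame(df$chrom, df$start, df$end,
                      paste0("peak_", seq_len(nrow(df))), 0L, ".",
                      df$signal, -1, -1, -1, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  np(landscape$ctcf_peaks, paths$ctcf)
  np(landscape$rad21_peaks, paths$rad21)
  write_loops_bedpe(sim$loops, paths$loops)
  write_cluster_records(clusters, paths$clusters)
  utils::write.table(landscape$ages, paths$ages, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(list(seed = seed), unclass(config)),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(landscape = landscape, sim = sim, clusters = clusters,
                 paths = paths))
}

#' Load a dataset bundle written by [make_dataset()]
#'
#' @param dir directory containing the bundle files.
#' @return List with `motifs`, `ctcf_peaks`, `rad21_peaks`, `loops`,
#'   `clusters`, `ages` and, when present, `truth`.
#' @export
load_dataset <- function(dir) {
  out <- list(
    motifs = read_motif_occurrences(file.path(dir, "motifs.tsv")),
    ctcf_peaks = read_narrowpeak(file.path(dir, "ctcf.narrowPeak")),
    rad21_peaks = read_narrowpeak(file.path(dir, "rad21.narrowPeak")),
    loops = read_loops_bedpe(file.path(dir, "loops.bedpe")),
    clusters = read_cluster_records(file.path(dir, "clusters.txt")),
    ages = read_ages(file.path(dir, "ages.tsv"))
  )
  tpath <- file.path(dir, "truth.tsv")
  if (file.exists(tpath)) {
    out$truth <- utils::read.delim(tpath, stringsAsFactors = FALSE)
  }
  out
}
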