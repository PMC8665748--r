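# loopgcp

Two-stage random-forest prediction of CTCF-mediated chromatin loops with
a network-transitivity feature.

## The problem

CTCF-anchored chromatin loops organize the genome into domains, but
mapping them (ChIA-PET, Hi-C) is costly, and the loop-extrusion model
only explains loops whose CTCF motifs face each other (*convergent*
loops). Many observed loops join motifs in *tandem* orientation. When two
loops share an anchor, their three anchors colocalize in space, so the
closing anchor pair can be captured as an indirect, transitively formed
loop — and tandem loops look exactly like such closures. `loopgcp` is for
computational genomicists who want to (i) predict CTCF loops from motif,
CTCF/RAD21 ChIP-seq and distance features alone, and (ii) quantify and
test the transitivity structure of loop networks.

## The method

Candidate loop anchors are CTCF motifs in mutual one-to-one overlap with
a CTCF ChIP-seq peak. Positive samples are observed loops whose anchor
regions each contain exactly one such anchor; negatives are random
anchor pairs of the same orientation class, distance-matched to the
positives by decile. A first-stage random forest scores each candidate
pair from anchor features (strand, motif score, CTCF/RAD21 signal, motif
age, one-hot 19-bp motif sequence), nine in-between summaries and the
genomic distance. The predicted probabilities define an edge-weighted
interaction network G(V, E, p), on which each edge's **graph connecting
probability** is

GCP(e) = max over paths between e's endpoints in G − e of ∏ p(e_i)
       = exp(− min over paths of Σ −log p(e_i)),

a nonnegative-weight shortest-path problem solved with Dijkstra's
algorithm (GCP = 0 for bridges). A second-stage forest retrains on the
base features plus GCP. Stage-one probabilities for training rows are
out-of-fold, so labels never leak into the network feature.

The package also provides loop-network transitivity statistics (local
clustering coefficients, k-clique counts, alternative path lengths,
degree-preserving edge-shuffle nulls), transitive-triple detection with a
multiway-contact-cluster colocalization Fisher test, frequency-threshold
profiles, and a synthetic data generator that emulates extrusion-formed
convergent loops plus transitive tandem closures so the entire pipeline
is testable without external downloads.

## Worked example

```r
library(loopgcp)

cfg  <- simulation_config()                      # 4 x 12 Mb, 300 anchors/chrom
land <- simulate_anchor_landscape(cfg, seed = 1)
sim  <- simulate_loops(land, cfg, seed = 2)
prep <- prepare_samples(land$motifs, land$ctcf_peaks, land$rad21_peaks,
                        sim$loops, land$ages, seed = 3)
prep
#> loop_dataset: 1200 valid anchors, 2180 samples
#>
#>              negative positive
#>   convergent      654      654
#>   tandem          436      436

feats <- assemble_feature_matrix(prep)           # 2180 x 172
ev <- cross_validate(feats$x, feats$labels, prep$samples[, c("a1", "a2")],
                     k = 10, params = forest_params(num_trees = 200),
                     seed = 11)
ev
#> loop_eval (within_cell, 10 folds)
#>  model     auroc      aupr  accuracy        f1
#>  basic 0.6264877 0.6168745 0.5798165 0.5864688
#>  final 0.7837766 0.7781426 0.7334862 0.7402756
```

The basic (stage-one) model sees only per-anchor and in-between signals;
the final model adds GCP, lifting mean ten-fold AUROC from ≈ 0.63 to
≈ 0.78 because transitive tandem loops are recognizable only through the
network. In the final model's Gini importances GCP ranks second, behind
only the aggregated motif-sequence block:

```r
m <- train_two_stage(feats$x, feats$labels, prep$samples[, c("a1", "a2")],
                     forest_params(num_trees = 200), seed = 7)
head(feature_importances(m)$final, 3)
#>          feature importance
#> 1 motif_sequence 0.42146802
#> 2            GCP 0.21345370
#> 3 L_rad21_signal 0.02915845
```

A command-line pipeline wrapping the same functions is installed as
`exec/loopgcp` (`simulate`, `prepare`, `features`, `train`, `predict`,
`evaluate`, `network-stats`, `triples`).

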