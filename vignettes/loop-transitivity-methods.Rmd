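---
title: "Predicting CTCF-mediated loops with network transitivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CTCF-mediated loops with network transitivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopgcp)
```

## The problem

CTCF-bound loop anchors partition mammalian genomes into loops and
domains. Loop extrusion explains *convergent* loops — cohesin enlarges a
loop until it is blocked at two CTCF sites whose motifs face each other —
but many observed loops join motifs in *tandem* orientation, which
extrusion alone does not produce. When two loops share an anchor, their
three anchors colocalize in space, so the closing pair of anchors can be
captured as an indirect, transitively formed loop. `loopgcp` turns that
observation into a predictive feature and a set of analyses:

1. a two-stage random-forest classifier for candidate anchor pairs,
2. a transitivity measure (GCP) on the predicted interaction network,
3. transitivity statistics of loop networks against degree-preserving
   nulls, and
4. a transitive-triple colocalization test against multiway contact
   (SPRITE-style) clusters.

## The model

### Candidate anchors and samples

A motif occurrence is a **valid anchor** when it is in mutual one-to-one
overlap with a CTCF ChIP-seq peak: the motif overlaps exactly one peak
and that peak overlaps exactly one motif. Both directions matter — a peak
covering two motifs identifies neither site unambiguously. Anchor pairs
on the same chromosome with motif-midpoint separation strictly inside
(10 kb, 1 Mb) are candidate loops; observed loops whose anchor regions
each contain exactly one valid anchor are the positives. Negatives are
random valid-anchor pairs of the same orientation class that do not
coincide with any observed loop, distance-matched to the positives by an
equal-count decile split of the positive distances (stable sort, so tied
distances cannot create empty bins) with per-bin sampling without
replacement. Distance is therefore uninformative by construction, which
is the point: it forces the classifier to use biology, not separation.
Convergent and tandem training sets are built independently; divergent
pairs are classified but excluded from training.

### Features

Per anchor: strand (+ as 1, − as 0), motif score, CTCF signal, RAD21
signal, motif age code, and the one-hot motif sequence (A, T, G, C as the
four unit vectors, concatenated: 76 columns for the 19-bp CTCF core).
Per pair: nine in-between summaries (motif score sum; CTCF signal sum,
plus- and minus-strand CTCF signal sums, where a peak inherits a strand
from its one-to-one matched motif and otherwise counts only in the
unsigned sum; motif counts total/plus/minus; RAD21 peak count and signal
sum) and the midpoint distance. An element is "in between" when it lies
entirely inside the open region between the two anchor motifs' inner
edges; containment rather than mere overlap keeps the anchors' own peaks,
which protrude into the region, out of the sums and makes the block
symmetric under anchor swap. The default schema is 172 columns (173 with
GCP). A `compat97` variant keeps a single shared motif block (the
element-wise OR of the two anchors' encodings), giving 97 columns with
GCP, for workflows that want one sequence block instead of two.

### GCP: graph connecting probability

Let $G(V, E, p)$ be the interaction network whose vertices are anchors,
whose edges are candidate loops, and whose edge weights $p(e) \in (0,1)$
are predicted loop probabilities. For an edge $e = \{u, v\}$,

$$\mathrm{GCP}(e) \;=\; \max_{\text{path} \in \mathrm{Path}(e)} \prod_i p(e_i)
\;=\; \exp\!\Big(-\min_{\text{path} \in \mathrm{Path}(e)} \sum_i -\log p(e_i)\Big),$$

where $\mathrm{Path}(e)$ are the paths between $u$ and $v$ in $G - e$.
Because $-\log p \ge 0$, the inner minimum is a nonnegative-weight
shortest-path problem solved with Dijkstra's algorithm. GCP quantifies
the transitive support for a loop: a pair that closes a triangle of
confident loops scores near the product of the two supporting edges,
while a bridge (no alternative path) scores 0 — the maximum over an empty
path set is defined as 0, matching the unweighted notion of an infinite
alternative path length. Probabilities are clamped to
$[10^{-6}, 1 - 10^{-6}]$ so the weights are finite and positive; positive
weights also guarantee shortest paths are simple, so no explicit
simplicity constraint is needed. `gcp_all()` recomputes per edge
(delete edge, one Dijkstra); at the package's design scale (thousands of
edges) this costs seconds, and no incremental shortcut is attempted.

### Two-stage training

Stage one fits a probability random forest (default 500 trees, Gini
impurity, square-root `mtry`) on the base features. Its predicted
probabilities weight the interaction network over **all** training
samples, positive- and negative-labelled alike — low-probability edges
contribute little by construction. Crucially, the probabilities used for
training rows are **out-of-fold** (internal 5-fold refit): in-sample
forest predictions are nearly equal to the labels, and feeding them into
the network would leak labels into GCP and inflate the second stage.
Stage two refits the forest on the base features plus the GCP column. At
prediction time, new edges are scored by stage one, a combined network
(training edges at their stored out-of-fold probabilities, new edges at
their stage-one probabilities, duplicate pairs keeping the maximum) is
built, GCP of the new edges is read off, and stage two emits the final
probability. Restricting the test-time network to training edges only is
available (`include_train_edges = FALSE`); including test edges is the
default because a cell type's loops support each other, not just the
training set's.

### Evaluation schemes

`cross_validate()` retrains the *entire* two-stage procedure per fold
under three schemes: `within_cell` (stratified random folds, default
k = 10), `across_chromosome` (folds are unions of chromosomes, never
splitting one; the fold count drops with a warning when chromosomes are
fewer than k), and `across_cell` (train on one sample set, test on a
second). Metrics are AUROC, AUPR (average precision), accuracy and F1 at
0.5. Gini importances are normalized per model; the 76 one-hot columns
are optionally aggregated into a single `motif_sequence` entry, since
ranked individually the per-base indicators understate the sequence's
joint contribution. `ablation()` cross-validates every requested
combination of the `base` (anchor scalars + distance), `motif` and
`inbetween` groups with and without the GCP stage.

## Transitive triples and colocalization

A transitive triple is a tandem pair (A, B) whose two anchors each
connect to a shared third anchor C; by default the two bridges must be
convergent (the extrusion-formed loops that do the pulling), with a
permissive any-orientation mode behind a flag. Multiway-cluster members
are assigned to their nearest anchor by midpoint distance (ties to the
lower coordinate), members farther than 5 kb are dropped, and a triple is
colocalization-validated when at least 20 clusters contain all three of
its anchors in one record. The association between being a positive
tandem loop and sitting in a validated triple is tested two-sided with
Fisher's exact test; the odds ratio uses the Haldane 0.5 correction when
a cell is zero.

## The synthetic study

The generator emulates the data-generating story the method assumes,
with defaults chosen once as the package's study conditions:

* four 12-Mb chromosomes with 300 anchors each, uniformly placed with a
  guaranteed 20-kb minimum spacing; strands fair coins; 19-bp motifs;
* every anchor backed by exactly one CTCF peak and, with probability
  0.9, a RAD21 peak; 10% decoy motifs/peaks violate the one-to-one rule
  to exercise the anchor filter;
* a latent per-anchor propensity $z \sim N(0,1)$ shifts the log-normal
  ChIP signal means (coupling 0.4) **and** scales loop formation, so the
  basic model is learnable but deliberately far from perfect;
* direct loops: convergent pairs accepted with probability
  $0.75\, e^{-d/250\mathrm{kb}}\, q_a q_b$, $q = \mathrm{logit}^{-1}(1+z)$;
* transitive loops: each closeable tandem pair of two direct loops
  sharing an anchor closes with probability 0.6 (the closing pair of two
  convergent loops through a shared outer anchor is always tandem); the
  coin is tossed once per unique closing pair and the first mediating
  anchor is recorded;
* noise loops: 5% of the true loop count, any orientation;
* PET frequencies: 2 + Poisson with means 20 (direct), 4 (transitive),
  2 (noise) — only the ordering direct > transitive is meaningful;
* clusters: each transitive triple emits Poisson(30) three-member
  clusters with ≤ 2 kb positional jitter (safely inside the 5-kb
  assignment rule), plus 300 random background clusters.

These defaults produce roughly 1,050 positive loops, hence ~2,100
balanced training samples. What the generator does **not** emulate:
sequence-specific motif information (sequences are random, so the motif
block is pure noise here), chromatin-state context, replicate structure,
and the heavy-tailed contact-frequency decay of real ChIA-PET libraries.
A passing test suite therefore demonstrates the *mechanics* — that GCP
recovers transitive structure and that the pipeline is correct and
reproducible — not that real-genome AUROC levels are reached.

## Numerical and scale choices

* All randomness flows from a single integer seed per entry point;
  forests run single-threaded with fixed seeds, so models, metrics and
  simulated bundles are bit-reproducible.
* Probability clamp $10^{-6}$; GCP log-domain consistency holds to
  $10^{-12}$; duplicate edges keep the maximum probability.
* The test suite runs the expensive checks at reduced but stated sizes:
  ten-fold CV with 150-tree forests over five simulated datasets for the
  two-stage benefit check, and twenty label permutations at n = 600 for
  the chance-level check. The package default stays at 500 trees.
* Degenerate inputs: empty motif/peak lists warn and return empty anchor
  sets; a distance bin with too few negative candidates takes what exists
  and logs the deficit; bridges have GCP 0; degree-below-2 nodes have
  clustering coefficient 0; fold counts shrink to the chromosome count.

## Known limitations

* `gcp_all()` is quadratic-ish (one Dijkstra per edge); fine up to tens
  of thousands of edges, not engineered for whole-genome Hi-C networks.
* The one-to-one anchor rule discards motifs in peak-dense regions;
  real CTCF clusters may lose genuine anchors that way (the original
  sample-generation recipe shares this property).
* The "ninety-seven"-column compatibility schema collapses the two
  anchors' sequences into one OR-ed block and so loses which anchor
  carries which base; the default schema keeps both blocks.
* Motif age is consumed as an opaque ordinal code; without an input
  annotation it is 0 and the feature is inert.
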