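---
title: "Scoring candidate biomarkers by network proximity: model and design notes"
author: "motiveRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring candidate biomarkers by network proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motiveRank)
```

## The model

`motiveRank` operationalizes a guilt-by-association principle: a candidate
protein is related to a disease process to the extent that it sits close,
in the protein interaction network, to the proteins known to effect that
process.  The package represents the disease as a `DiseaseMap` — a list of
pathophysiological processes ("motives"), each with a causal level
(causative / symptomatic / both) and a curated effector protein set — and
the interactome as a `KnowledgeGraph` assembled from layer-tagged edge
lists (physical, signaling, metabolic, regulation).  The disease's general
characterization is carried as a pseudo-motive (`das_general`) with its own
effector set, so scoring and counting treat all processes uniformly.

All proximity computations run on the **collapsed simple undirected
graph**: a protein pair supported by several layers counts once, self-loops
are dropped at load, and regulatory direction is kept only as edge
metadata.  The layers attest provenance; nothing in the published scoring
semantics assigns them directed or weighted roles, and collapsing keeps hop
distances and walk probabilities comparable across layers.

### Features

For candidate $c$ and effector set $M$:

* $d_{\min}(c, M)$ and $d_{\mathrm{mean}}(c, M)$ — shortest-path hop
  distances (minimum and mean over $M$).  If $c \in M$, $d_{\min} = 0$ and
  the candidate is excluded from the set for the remaining quantities.
  Unreachable pairs receive the sentinel `Inf`, converted to a finite cap
  (largest-component diameter + 1) only when the feature vector is built —
  never stored as a magic constant in the graph.
* $\mathrm{RWR}(c \mid M)$ — the stationary probability at $c$ of a random
  walk restarting at $M$ (uniformly) with probability $r = 0.3$ per step,
  transitions uniform over neighbors, walkers on isolated nodes restarting.
  Solved by power iteration to a sup-norm tolerance of $10^{-10}$; the test
  suite verifies agreement with a dense direct linear solve to $10^{-8}$ on
  graphs of up to 50 nodes.  $r = 0.3$ is the conventional restart for
  network propagation on interaction maps: small enough to diffuse past
  immediate neighbors, large enough to stay local to the seed module.
* Jaccard overlap of the candidate's neighborhood with the union
  neighborhood of $M$.
* $\log(1 + \mathrm{degree})$ — so the predictor can learn to discount hub
  promiscuity.

### Predictor

The relationship predictor is a single-hidden-layer feed-forward neural
network, 5 features → 8 logistic hidden units → 1 logistic output, trained
by full-batch gradient descent (learning rate 0.5, momentum 0.9, weight
decay $10^{-4}$, 600 epochs) under a fixed seed, on standardized features.
This is the smallest architecture that can express interactions among five
features; with a few hundred training pairs there is nothing for a deeper
network to learn, and the deterministic full-batch fit keeps retraining
reproducible bit for bit.  A stratified 75/25 split supplies the held-out
accuracy reported in the model metrics; the shipped weights are then refit
on all pairs.  The test suite cross-checks the network against an
independent logistic-regression oracle on the same features: both must
separate proximal from distal pairs, confirming the signal lives in the
features rather than in the fit.

### Truth table

Positives are all (effector, its motive) assignments present in the graph.
Negatives are sampled per motive, degree-matched to a positive (same
$\lfloor \log_2 \mathrm{degree} \rfloor$ bin, nearest occupied bin as
fallback) at hop distance ≥ `minNegDistance` from the motive's effector
set, `negPerPos = 2` per positive.  Two negatives per positive give the
classifier a better picture of the background without drowning the
positive class.

### Calibration

Raw network outputs are not comparable across motives or degree regimes,
so each is converted to an **empirical p-value** against a permutation
null: raw scores of $N = 1000$ proteins drawn (with replacement) from the
candidate's log2-degree bin, excluding the motive's effectors.  One null
is built and cached per (motive, degree-bin) pair — a full
candidate-by-candidate permutation would repeat identical work at desk
scale.  The estimator $p = (1 + \#\{\mathrm{null} \ge \mathrm{raw}\}) /
(N + 1)$ never returns 0 and counts ties conservatively, so band
exceedance rates can only undershoot their nominal levels.

The 0–100 score is a piecewise-linear map in $\log_{10} p$ through the
published anchors $(0.01, 92),\ (0.05, 78),\ (0.15, 63),\ (0.25, 38)$,
extended to $(0.001, 100)$ above (clamped at 100) and to $(1, 0)$ below.
Categories use closed lower bounds — a score of exactly 92 is *very high* —
following the prose definition ("≥ 92") over the table's
strict inequality; the banding is centralized in `scoreCategory()` so the
convention lives in one place.

### Prioritization rules

A protein is **strong** if any scored motive reaches the medium-high band
(score ≥ 63), **medium** if its best band is medium, **low** otherwise.
The multi-motive selection keeps proteins strong in ≥ 3 processes; whether
the general characterization counts as a process is the `includeGeneral`
flag, default `TRUE` — with it, transthyretin (strong in oxidative stress,
inflammation and the general characterization only) qualifies, matching
its presence in the published selection.  Ranking is by best score
descending with ties broken by accession; the printed table has no ties at
its precision, so the tie-break is a package convention for total
ordering.  *Novel* candidates are selected proteins with no effector flag
on any scored motive.

## The synthetic study generator

`simulateStudy()` emulates the statistical structure the method assumes:
disease processes are proximal neighborhoods in a scale-free interactome.

* **Network** — preferential attachment (seed graph one edge, each new node
  attaching to `edgesPerNode = 3` existing nodes by degree), 500 nodes by
  default: heavy-tailed degrees and small diameter, like curated
  interactomes at pathway scale, while keeping every test and the
  acceptance run at desk scale.
* **Motives** — 4 disjoint connected modules of 8–15 nodes, densified with
  intra-module edges to internal density ≥ 0.3, so effector sets are
  genuinely cohesive neighborhoods.
* **Candidates** — 5 related candidates per motive, added as new nodes wired
  into their module with 3 edges (hop distance exactly 1); 20 unrelated
  candidates chosen among existing nodes at distance ≥ 2 from every module,
  so their degrees are realistic for the degree-matched nulls.

The separation floors (`unrelatedMinDistance = 2`, `minNegDistance = 2`)
reflect a structural fact of small-world networks: in a 500-node
preferential-attachment graph, the 2-hop neighborhoods of four planted
modules cover almost every node, so floors of 3 or more leave essentially
no eligible proteins.  Two hops versus direct attachment is also the
honest version of the decision problem — trivially separated classes would
say nothing about the scorer.

What the generator does **not** emulate: literature-curation bias
(effectors of well-studied processes have inflated degrees), multi-layer
edge redundancy, annotation errors in effector sets, and candidates whose
relatedness is mediated by paths the interactome does not contain.  Passing
tests on synthetic studies therefore validate the machinery — feature
computation, calibration, selection arithmetic — not the biological
fidelity of any particular curated map.

## Numerical choices and degenerate inputs

* All stochastic stages take explicit integer seeds; the pipeline derives
  per-stage seeds from one master seed by fixed offsets, and per-null seeds
  from (motive index, degree bin), all kept within 32-bit range.
* A candidate absent from the graph receives the sentinel feature vector
  (capped distances, zero walk mass, zero overlap) plus a
  `missing_from_graph` QC flag; it is scored, not dropped, so report shapes
  stay stable.
* An empty degree bin falls back to the nearest occupied bin with a
  warning.  A candidate that *is* the entire effector set receives the
  fixed proximal vector.  Empty candidate lists, empty score matrices and
  headers-only reports are all defined outputs.
* Fixture matrices are sparse: only printed (strong-band) cells are
  non-`NA`, and all counting operates on present cells only.

## Known limitations

* The packaged effector sets are the partial subset recoverable from the
  printed multi-motive table; the full published curation (168 effectors)
  is not public, so per-motive count tables from scratch are not expected
  to reproduce the published absolute counts — the package verifies their
  internal arithmetic and the selection logic instead.
* The published score itself comes from a proprietary modeling platform;
  the permutation-null calibration here is this package's own construction,
  designed so the published score-to-p correspondence holds by definition
  of the scale, with exceedance rates at or below nominal (verified by the
  acceptance check at 25 000 null draws).
* With a sharply separating predictor, tie-heavy nulls make empirical
  p-values conservative; scores compress toward the low bands for
  background proteins.  That is the safe direction for prioritization.

## Problem sizes used in the checks

The test suite runs oracle comparisons on graphs of ≤ 50 nodes, module and
candidate contracts on 200–300-node networks, and recovery (AUROC ≥ 0.9
over 5 seeds) plus calibration on the 500-node default study; the
acceptance script scores 5000 fresh null candidates per process at 1000
draws per cached null.  These sizes exercise every code path in seconds to
a few minutes on one CPU.
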