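---
title: "Homological scaffolds of weighted connectivity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homological scaffolds of weighted connectivity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homscaffold)
```

## The problem

Functional connectivity (FC) matrices from resting-state fMRI are fully
connected, weighted and signed: every pair of regions carries a
Fisher-z-transformed Pearson correlation. Standard graph analysis binarizes
such a matrix at an arbitrary density, discarding the weak edges entirely
and reducing the data to dyadic (edge-by-edge) structure. Persistent
homology offers a complementary view: it uses *all* edge weights, and it
describes mesoscopic structure — cycles of length four or more that are not
filled in by triangles — rather than pairwise links. This package
implements that analysis end to end: the weight rank clique filtration, H1
persistent homology with representative cycles, the frequency and
persistence homological scaffolds, the nodal persistence scaffold strength
(PSS), and the comparison workflow against the standard binary and weighted
centralities.

## The model

**Weight rank clique filtration.** Starting from disconnected nodes, the
nonzero edges enter in descending weight order. After each addition the
clique complex is taken: every triangle whose three edges are present is
filled as a 2-simplex. A minimal closed path of length > 3 that is not
bounded by filled triangles is a 1-dimensional hole (an H1 class). As edges
accumulate, a hole appears at a *birth* step $\beta_i$ and is eventually
filled at a *death* step $\delta_i$; its *persistence* is
$\pi_i = \delta_i - \beta_i$. Time is discrete: one step per distinct
weight level, so tied weights share a step. We chose weight *levels* rather
than individual edges as the clock because the level is the natural unit of
simultaneity — a tie means the data do not order those edges — and the
classic six-node illustration of this method counts its steps the same way
(five distinct weights, five steps).

**Pairing and representatives.** The implementation is the standard GF(2)
boundary reduction specialised to dimension 1. Edges are processed in
filtration order; an edge joining two components extends a spanning forest,
while an edge closing a loop creates a class whose frozen representative is
that edge plus the forest path between its endpoints at birth. Triangles
enter at the step of their latest edge and are reduced as boundary columns;
each reducible triangle kills the youngest unpaired class (the standard
convention). Within a step, edges are processed before triangles, both in
lexicographic order; consequently a chord that instantly completes a
triangle creates a zero-persistence pair, which is discarded. Freezing the
representative at birth mirrors the behaviour of the established Java
persistent-homology implementations: a class keeps one edge set for its
whole lifetime even though, as an equivalence class, it could be contracted
or split. Because this choice makes the scaffolds representative-dependent,
`classify_cycle_deaths()` replays each class's lifetime and labels it
`pure-triadic` (it only ever shrank by triangle closures) or
`split-involved` (a chord divided it), which is the diagnostic a careful
reader of a scaffold should consult.

**Scaffolds and PSS.** The frequency scaffold weights each edge by the
number of representatives containing it; the persistence scaffold weights
it by their summed persistences. Both are edge-centrality summaries and are
themselves weighted networks. The PSS of a node is its strength (row sum)
in the persistence scaffold — a scalar that aggregates the persistence of
every cycle running through the node.

**Standard metrics.** For comparison the package provides degree,
unnormalized betweenness, local efficiency (mean inverse shortest-path
distance between a node's neighbours, computed inside the
neighbourhood-induced subgraph, prefactor $2/(n(n-1))$), node strength,
weighted betweenness and weighted local efficiency (edge length $1/w$ by
default, nonpositive weights unusable), the participation coefficient
$1 - \sum_C (k_{Ci}/k_i)^2$, and Louvain community detection. One printed
form of the local-efficiency formula circulates with an extra global $1/N$
prefactor; we follow the Brain Connectivity Toolbox convention without it,
since the quantity is an average over neighbour pairs only. Betweenness,
weighted shortest paths, and Louvain go through igraph; the formula-level
metrics are computed directly and verified against brute-force oracles in
the test suite.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `order_mode` | `signed-descending` | Edge ordering key. Group-level Fisher-z FC is predominantly positive, so signed and absolute orderings rarely differ there; both are provided because the choice matters for strongly signed matrices and the literature does not pin it down. |
| `open_policy` | `flag` | A class that never dies (possible only for incomplete matrices) gets persistence `n_steps + 1 - birth` and an `open` flag; `exclude` drops such classes. On fully connected input every class dies, so the default only matters for sparse graphs. |
| density grid | `0.10–0.60 by 0.05` | Eleven proportional-thresholding densities for the binary sweep. |
| `community_density` | `0.40` | Density at which Louvain communities are detected for the participation coefficient — an intermediate density where module structure is neither fragmented nor washed out. |
| hub rule | mean + 1 sd | A node is a hub when its metric value strictly exceeds the distribution mean by more than one sample standard deviation. |

## Numerical choices

* **Fisher transform clipping.** Correlations are clipped to
  $|r| \le 1 - 10^{-12}$ before `atanh`, so perfectly correlated regions
  give a large finite weight instead of infinity.
* **Asymmetry tolerance.** Input matrices asymmetric by at most $10^{-9}$
  (floating-point artifacts of external tools) are symmetrised by
  averaging; larger asymmetry is an error.
* **Proportional thresholding.** The retained edge count is
  `density * n(n-1)/2` rounded half-up, with the product snapped to 9
  decimals first so that binary floating point cannot move a half-way case
  (e.g. `0.10 * 4005` evaluates to `400.50000000000006`). Ties at the
  cutoff resolve lexicographically by node pair, making the retained sets
  deterministic and nested across densities.
* **Birth/death on the step axis.** Persistence is measured in integer step
  indices; the step-to-weight map is kept in the filtration object for
  callers that want a weight-valued axis. Sub-gap jitter of the weights
  therefore leaves the entire analysis unchanged, the discrete counterpart
  of the stability theorems for persistence diagrams.
* **Integration over density.** The trapezoidal rule on the eleven grid
  points turns each node's metric-versus-density curve into one
  threshold-free scalar.
* **Correlation p-values** come from the two-sided t approximation with
  $n-2$ degrees of freedom; degenerate (zero-variance) metric vectors at a
  given density yield an `NA` row in the bundle rather than an error.
* **Determinism.** Every stochastic step (simulation, Louvain node order)
  is seeded; `run_full_analysis()` with a fixed seed and configuration
  serializes to a byte-identical report.

## Synthetic data: what it emulates and what it does not

`simulate_fc_study()` emulates the FC-construction pipeline of a
multi-subject resting-state study: 90 regions in 6 modules, 16 subjects,
140 timepoints (roughly seven minutes at a 3 s sampling interval), region
time series drawn i.i.d. across time from a zero-mean Gaussian with
exchangeable block covariance (within-module correlation 0.6, between 0.1),
per-subject Fisher-z correlation matrices, and an element-wise group
average. It reproduces the *block correlation* structure that drives the
downstream analysis, but deliberately omits hemodynamics, temporal
autocorrelation, motion and physiological confounds, and spatial hierarchy.
One consequence worth knowing: with a shared module factor, the sampling
noise of cross-module correlations is correlated across region pairs of the
same module pair, so proportional thresholding concentrates the retained
cross edges on a few module pairs and modularity optimisation may merge
modules — an emergent property of factor-model noise, not a bug in the
community detection.

`planted_bridge_network()` is the construction-controlled fixture for the
qualitative claim that high-PSS nodes bridge communities rather than sit in
dense neighbourhoods. Its weights fall in four disjoint bands: dense
within-module near-cliques (0.75–1), a chordless *ring* over one designated
bridge node per module (strongest cross band), other bridge-mediated
cross-module pairs (intermediate), and weak background on everything else,
including the ring's diagonals. The ring is the load-bearing choice: it
guarantees that the spanning forest of the filtration crosses modules only
at bridges, and that the closing ring edge opens a long-lived
inter-module hole whose representative passes *every* bridge. Earlier,
simpler constructions fail quietly — a complete strong bridge-bridge band
instantly kills later cross-module cycles through bridge-bridge-interior
triangles, and a single undifferentiated cross band lets forest paths
enter a module past its bridge — which is why the band structure is pinned
down by tests. On this fixture, bridge nodes exceed the non-bridge median
in PSS and participation coefficient and fall below it in binary local
efficiency at density 0.40 in at least 95 of 100 seeds; passing that test
demonstrates the directional structure of the method on data built to
contain it, not the effect size one would see on real fMRI.

`toy_network()` fixes the canonical six-node example: five weight levels,
two cycles (births at steps 2 and 3, both deaths at step 5, persistences 3
and 2), edge *(c, f)* top-ranked in both scaffolds, and PSS maxima of 10 at
*c* and *f*. The published illustration of this example does not print the
edge weights; the assignment used here (5 on *ab, bc, cf, cd, de*; 4 on
*fa*; 3 on *ef*; 2 on *bd*; 1 on *ac, ce*) was constructed to satisfy every
stated property of the example and is validated step by step against the
brute-force Betti oracle in the tests. Any other assignment with the same
ordering structure yields the same barcode.

## Problem sizes

The default test and acceptance runs use: the 6-node toy; random networks
of 5–10 nodes (100 seeds) for the step-by-step Betti oracle; the named
small-graph suite (n ≤ 8) for brute-force metric checks; 50 fully
connected 20-node networks for the death guarantee; 100 planted-bridge
networks of 24 nodes for the sign structure; and one simulated 90-region,
16-subject study for the end-to-end determinism check. The persistence core
is compiled (Rcpp), so the full 90-node pipeline — about 4,000 edges and
117,000 triangles — runs in a few seconds.

## Known limitations

* Homology is computed in dimension 1 only; higher-dimensional scaffolds
  and a higher-dimensional PSS are natural extensions but out of scope.
* Scaffolds inherit the representative-choice ambiguity discussed above;
  they are informative but not canonical, and the death-classification
  diagnostic should accompany any interpretation of individual scaffold
  edges.
* Negative weights are preserved in strength sums and in the
  signed-descending ordering, but are unusable for weighted shortest paths
  (a negative correlation is not a short distance).
* The edge-list text dialect cannot represent isolated nodes; use the
  matrix dialect when node order must round-trip for arbitrary networks.
* No partial-correlation control for node degree is implemented; users who
  need degree-controlled associations with PSS must compute them from the
  exported metric tables.

## A worked example

```{r toy}
net <- toy_network()
barcode <- compute_persistence(weight_rank_filtration(net))
tidy(barcode)

sp <- scaffold(barcode, "persistence")
scaffold_edge_ranking(sp, top_k = 3)
pss(sp)
```

```{r full, eval = FALSE}
study <- simulate_fc_study(seed = 1)
res <- run_full_analysis(study$group, seed = 1)
glance(res)
autoplot(res)
```
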