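---
title: "Methods: PCST-based TF inference and image-based screening readouts"
author: "mechanoScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCST-based TF inference and image-based screening readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoScreen)
```

# The scientific problem

Fibroblasts in 3D culture activate under compressive load, and an
ERK-dependent transcriptional program is one driver of that activation.
The computational task is to work backwards from two differential-
expression comparisons — (i) 2× load vs unloaded control and (ii) ERK
inhibition (PD98059) under 2× load vs 2× load alone — to the transcription
factors most likely to relay the mechanical signal, and then to score
inhibitors of those TFs with image-based readouts: how far spheroids
spread, and how nuclear chromatin compaction changes.

# The network model

## Tripartite structure

Three node classes form the network. Transcriptional regulators that have
protein–protein interaction (PPI) information are **TF nodes**; all other
PPI proteins are **Protein nodes**; regulated target transcripts are
**RNA nodes**. RNA nodes are namespaced (`GENE:rna`) so a gene that is
both a PPI protein and a regulated transcript contributes two distinct
nodes — without this, a TF regulating its own transcript would create a
self-edge and corrupt the topology.

PPI edges carry cost $-\log(s/1000)$, where $s \in (0, 1000]$ is the
STRING-style integer confidence: perfect-confidence links are free,
weak links expensive. A score of 0 would mean infinite cost and is
rejected. TF→RNA edges carry cost zero: once a TF is paid for, its known
regulatory links are free. The logarithm base (default 10, natural log
available) only rescales all PPI costs by a constant; the prize
multiplier $\beta$ absorbs the same constant, so the choice is a
convention, not a model decision.

## Prizes

A gene becomes a target (RNA node) when it is significantly upregulated
under load **and** significantly downregulated under ERK inhibition; its
prize is $(|\mathrm{log2FC}_{up}| + |\mathrm{log2FC}_{down}|)/2$.
Load-upregulated genes give their log2FC as the prize of the
corresponding Protein/TF node (0 when absent). The DE significance cutoff
is adjusted p < 0.05 by default with no fold-change floor; the DE tables
are inputs, and the cutoffs that produced the published gene-set sizes
belong to the upstream RNA-seq analysis, so both are exposed as
parameters rather than hard-coded.

## The optimization

We adopt the standard unrooted Goemans–Williamson prize-collecting
objective,

$$\min_{F}\; \sum_{e \in F} c(e) \;+\; \beta \sum_{v \notin F} p(v),$$

over forests $F$ with at most `numComponents` trees (default 1: a single
connected regulatory network). Equivalently the solver maximizes the net
value $\beta\,p(F) - c(F)$. This is the formulation used by the
established omics-network-integration tools built on `pcst_fast`-style
solvers, which this package's solver replaces with a self-contained
implementation:

* **Exact oracle** (`solvePCSTExact`): enumerates all node subsets (guard:
  15 nodes), connects each subset by a minimum spanning forest of its
  induced subgraph, and returns the global optimum. Ties break toward
  fewer nodes, then the lexicographically smallest id set, making outputs
  bit-reproducible.
* **Heuristic** (`solvePCST`): GW moat growing — clusters grow dual
  "moats" until an edge goes tight (clusters merge) or a cluster's prize
  surplus is exhausted (it deactivates) — produces a candidate forest.
  Every candidate tree is then **strong-pruned**: a dynamic program on the
  tree, evaluated from every root, that removes all subtrees of
  non-positive net value and is exact for a fixed tree. Pruned minimum-
  spanning-tree backbones of each graph component are added as further
  candidates, and the best disjoint positive-value trees win. The
  heuristic never reports a better objective than the exact optimum (it
  is a feasible solution) and matches it on 95–97% of small random
  instances in the shipped tests.

`pruneSolution` additionally exposes plain leaf pruning (drop a leaf when
$\beta p < c$ of its attaching edge), which never increases the objective
and is idempotent.

TFs are then ranked by the number of selected RNA targets reachable
through selected TF→RNA edges (`countTFTargets`, within the solution by
default — a flag counts against the full network instead, since either
reading is defensible), then by `|log2FC|` under load, then
alphabetically. `enrichTFTargets` offers a hypergeometric set-overlap
enrichment with BH adjustment as a transparent, clearly-labelled
alternative to motif-based regulon tools, which are out of scope.

# Imaging readouts

All percentiles and quartiles in the package use one convention: linear
interpolation between order statistics (R `quantile` type 7). The choice
is stated because it moves `i80/i20` in the third decimal; fixing a single
convention everywhere keeps network statistics, chromatin metrics and box
plots mutually consistent.

* **Segmentation**: global Otsu threshold, hole filling, and a
  distance-transform watershed to split touching nuclei; objects under
  `minArea` (default 100 px) are discarded.
* **i80/i20**: ratio of the 80th to 20th intensity percentile within a
  nucleus; ≥ 1 by construction and invariant to multiplicative intensity
  rescaling, hence insensitive to illumination and bit depth. Nuclei
  with a zero 20th percentile (after flooring negatives at 0) report a
  missing value rather than an infinite ratio.
* **Otsu foci**: per-nucleus Otsu threshold (illumination varies across
  fields, so thresholds are not shared), connected components ≥
  `minFocusArea` (default 5 px). The implementation scans every cut
  between distinct values, which *is* the exhaustive between-class
  variance search; the test oracle re-derives it naively.
* **Peripheral fraction**: the shell is the set of nucleus pixels within
  `shellWidth` (default 3 px) of the boundary by Euclidean distance
  transform; shell and core partition the focus pixels exactly, so the
  peripheral and core fractions sum to 1.
* **Spread area**: Otsu foreground → morphological closing (disc radius
  5 px) → hole filling; the spread area is the area of the resulting
  union of the spheroid and its migrating cells. The core is reported
  independently, as the largest connected component of the brighter
  foreground class (second Otsu pass within the foreground), because the
  package makes no assumption about how a "spheroid center" was defined
  upstream. The **cytoskeleton area ratio** is actin-positive area
  outside the core over core area; Otsu thresholding makes it invariant
  to uniform rescaling.

# Screen statistics

Groups are compared with the unpaired two-tailed **pooled-variance**
Student t test (a Welch flag exists), each condition vs the 2× load
reference. Box summaries use type-7 quartiles and whiskers at the extreme
data points within 1.5·IQR of the quartile box. Stars use strict
thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, else `ns`.
No multiple-testing correction is applied across conditions — matching
the screen's per-condition reporting — but the report carries a BH column
(`p_bh`) alongside so readers can judge both. Testing is per measurement
unit (per nucleus / per spheroid); aggregating to per-field means first
is the caller's choice by summarizing before `buildScreenReport`.

# Synthetic benchmarks: what they emulate, and what they do not

The generators define the study conditions for all tests:

* `generateNetworkBenchmark` (defaults: 60 background proteins, 8 TFs of
  which 2 planted with 6 disjoint targets each, one upstream hub, PPI
  density 0.06, background scores U[150, 700], planted cascade scores
  U[800, 999], planted |log2FC| half-normal(2, 0.5), noise log2FC
  N(0, 0.3), 40 pure-noise genes, decoy regulons of 8 background genes
  plus 2 planted targets). Planted scores are high but background scores
  are not negligible, so cascade recovery is a real optimization outcome,
  not a tautology; decoy TFs can reach planted targets, so ranking has
  something to demote. What it does not emulate: scale (a real STRING
  network has ~10^4 nodes), correlated expression noise, and the
  composite evidence channels behind STRING scores.
* `generateNucleusImage` (256×256 px, 5 nuclei of semi-axis 18–26 px,
  4 disc foci of radius 2.5–4 px at 3× nuclear intensity, smooth texture
  sd 300, noise sd 200 on a 16-bit scale, blur σ = 1 px): foci are
  uniform discs softened only by the image-level blur, so their
  thresholded footprint matches the planted area; focus centres fall in
  the peripheral shell with probability `peripheralBias`. Real chromatin
  texture is fractal and anisotropic; these images only exercise the
  metric definitions, so passing tests certify the *measurements*, not
  biological realism.
* `generateSpheroidImage` (512×512 px, core radius 60 px, migration
  radius 120 px, migrating-cell density 0.006 cells/px² of annulus —
  cell count scales with the colonized area, emulating progressive
  outward migration). No point-spread function or 3D projection effects
  are simulated.

Every generator is a pure function of its parameters and seed.

# Numerical choices and degenerate inputs

* Solver tolerance 1e-12 for tie detection; objectives reproduce from
  selected sets to 1e-9 in tests.
* `-log(1000/1000)` is normalized to `+0` so cost tables never print
  negative zero.
* Constant images: segmentation warns and returns an empty mask; Otsu
  refuses ("no threshold"); spread area refuses ("no foreground").
* Empty DE intersections warn and return an empty prize map — the
  pipeline continues and produces an empty network rather than failing.
* Zero pooled variance is an error (the t statistic is undefined), as is
  a score of 0 in the cost transform (infinite cost).

# Problem sizes in the shipped tests

Oracle-vs-heuristic agreement uses 200 random connected graphs of 4–10
nodes; planted-TF recovery uses 50 benchmark seeds (~80-node networks);
Otsu is checked against brute force on 100 random nuclei; peripheral-bias
monotonicity uses 20 seeds × 5 nuclei; the t-test null calibration uses
10,000 simulations. These sizes give stable pass/fail behavior for the
stochastic properties while keeping the whole suite under a minute.

# Known limitations

* The heuristic PCST has no approximation-factor guarantee as
  implemented; its quality is certified empirically against the exact
  oracle on small instances only.
* Gene identifiers are assumed pre-harmonized between the PPI and
  TF–target sources (species prefixes are stripped, nothing more).
* `numComponents > 1` selects the best disjoint candidate trees greedily;
  for k > 1 the result can be further from optimal than the single-tree
  default.
* Image analysis is strictly 2D; confocal stacks must be projected
  upstream, and the reader deliberately rejects multi-page TIFFs rather
  than guessing a projection.
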