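---
title: "Nerve-based topological comparison of 3D cellular architectures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nerve-based topological comparison of 3D cellular architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervetopo)
```

## The problem

Two cohorts of segmented 3D organs — say, ovules of two species fixed at the
same developmental stage — differ in how their cells are packed, even when
they look alike grossly. `nervetopo` detects and quantifies such differences
directly from labeled segmentation volumes, without access to the original
microscopy, by comparing the *topology* of cell contacts rather than cell
geometry.

## The nerve of a segmentation

Each cell of a labeled volume becomes a vertex. Every set of $k+1$ cells that
meet at a common point contributes a $k$-simplex: two adjacent cells give an
edge, three mutually meeting cells a triangle, four a tetrahedron. The
resulting downward-closed family of simplices — the nerve — generalizes the
region adjacency graph (its 1-skeleton) by retaining the higher-order contact
information needed to reconstruct the local polyhedral structure of each
cell. For a Voronoi tessellation of generic points, the nerve is exactly the
Delaunay triangulation, which gives us an independent brute-force oracle (the
empty-circumsphere test) against which the whole voxel pipeline is validated.

In a hard voxel segmentation no two cells literally share a voxel, so "cells
that meet" is evaluated on the dual grid: under the default `block2` scheme,
every $2\times2\times2$ block of voxels contributes a simplex on the distinct
cell labels it contains, plus all sub-simplices. This reproduces the Delaunay
complex on generic Voronoi inputs and captures all higher-order intersections.
Its one caveat is that two cells meeting only at a grid corner still produce
an edge; the `pairwise_face` scheme (strict 6-connectivity, the unweighted
region adjacency graph) is available when that is unwanted. Voxel spacing is
deliberately ignored: anisotropy deforms geometry but not incidence.

## Face-vectors and feature vectors

The *vertex star* of a cell is the set of simplices containing it; the
*face-vector* $(c_0, c_1, c_2, \dots)$ counts the $k$-simplices in the star.
A hexagonal cell surrounded by six neighbours has face-vector $(1, 6, 6)$:
one vertex, six edges, six triangles. For an interior cell of a generic 3D
tessellation the face-vector has the form $(1, x_2, x_3, x_4)$, where
$x_2/x_3/x_4$ count the faces/edges/vertices of the cell's polyhedron, so
Euler's formula forces $x_2 - x_3 + x_4 = 2$. Cells touching the image
border are retained but their stars are truncated, so the relation is not
expected for them.

A sample (one organ, or one tissue of one organ) is summarized by the
proportions of its cells falling in each face-vector class. Because
proportions are only comparable over a common enumeration, the *alphabet* of
face-vector classes is always built from the union of all samples in a
comparison; it is ordered deterministically (zero-padded, lexicographic).
By default the alphabet is per comparison — mirroring a per-stage,
per-tissue analysis — and a pre-built global alphabet can be passed to
`feature_matrix()` when rows must be comparable across comparisons.

## The two-sample test

Cohorts of feature vectors are compared with the Baringhaus–Franz (Cramér)
statistic: inter-cohort Euclidean distances enter positively, intra-cohort
distances negatively, through the kernel $\phi(z) = \sqrt{z}/2$ applied to
squared distances. With this default kernel the statistic is a scaled energy
distance: non-negative, zero exactly when the empirical distributions
coincide, large under the alternative. Any positive rescaling of the kernel
rescales the statistic but leaves resampled p-values unchanged; $\phi$ is a
plug-in argument.

P-values are estimated by resampling the pooled sample, with the plain
proportion of replicates at or above the observed statistic — no $+1$
correction, so a statistic exceeding every replicate reports an estimated p
of exactly zero. Two modes exist:

* **permutation** (default): the pooled $m+n$ vectors are randomly re-split
  into groups of $m$ and $n$. Under the null the observations are
  exchangeable, so this is exact up to Monte-Carlo error.
* **ordinary_bootstrap**: the pool is resampled with replacement. In the
  regime this package targets — small cohorts (around 10 samples) of sparse
  high-dimensional proportion vectors whose supports barely overlap — the
  duplicates created by with-replacement draws systematically inflate the
  replicate statistics, and the mode becomes so conservative that null
  p-values rarely drop below about 0.2. It is kept as an option because it
  is the classical default of this test, but it is not the package default
  for exactly this reason.

The per-(stage, tissue) p-values of `run_comparison()` are reported raw,
against the conventional 0.05 line, with the number of tests recorded in the
run manifest; no multiplicity adjustment is applied, and users scanning many
stages and tissues should keep that in mind. The *spread* of a cohort (mean
pairwise Euclidean distance among its feature vectors, over unordered pairs)
is reported alongside, and `pca_project()` provides the standard
column-centred, unscaled principal-component view (proportions share a
scale, so variance scaling is unnecessary; cohorts are pooled before
projection). PCA signs follow a deterministic convention: each component's
largest-magnitude loading is positive.

## Synthetic tessellations and what they do (not) show

All tests run on synthetic data with known ground truth:

* `voronoi_bulk` — seeds spread by best-candidate sampling in the interior
  of the box (15% wall margin), each voxel labeled by its nearest seed. This
  emulates a bulky, isotropic tissue such as a chalaza.
* `weighted_voronoi` — additive power weights whose dispersion inflates the
  realized cell-volume CV, enabling CV-driven cohort contrasts.
* `layered_sheet` — seeds on jittered 2D grids stacked in parallel layers
  (jitter 10% of the cell pitch), emulating the regular sheet architecture
  of integument-like epithelial tissues.
* `make_hex_fixture()` — the seven-cell hexagonal worked example with
  face-vectors $(1,6,6)$ (centre) and $(1,3,2)$ (ring).

**Genericity at finite resolution.** For the Delaunay-oracle comparisons the
seed set must be generic: no five points near-cospherical. A purely
numerical tolerance is not enough, because a pair of Voronoi vertices closer
together than one voxel block cannot be resolved on the grid: the block that
straddles both sees five labels at once and reports a spurious 4-simplex,
and the nerve would change under grid refinement. The generator therefore
rejects (and redraws, up to 200 times) seed sets whose empty-circumsphere
centres are closer than 2.5 voxels, in the ≤ 25-seed regime where the
$O(n^4)$ screen is affordable and the oracle applies. With this screen in
place the block2 nerve of a 15-seed, $64^3$ Voronoi volume equals the
brute-force Delaunay complex on interior cells, satisfies the Euler relation
for every interior cell, and is invariant under doubling the resolution.
Cohort-level studies (where no oracle is involved) skip the screen.

Synthetic tessellations share the idealized contact topology of real
segmentations but none of their biology: no cell growth, no division, no
wall curvature, no segmentation errors, and cell-volume laws are lognormal
by construction. Passing tests therefore validate the *machinery* —
construction, features, statistics — not any claim about real organs.

## Study conditions used by the acceptance checks

Chosen once, as realistic small-scale stand-ins, and fixed:

* Delaunay oracle: 15 seeds, $64^3$ voxels, 15% margin (runs in ~1 min).
* Null calibration: identical `voronoi_bulk` generators, 30 cells in
  $20^3$ voxels, cohorts of 10 vs 10, $B = 200$ replicates, 200 simulation
  runs. The empirical type-I error at the 0.05 line should sit near nominal
  (the permutation mode achieves this; see above for why the bootstrap mode
  does not).
* Architecture discrimination: `voronoi_bulk` vs 3-layer `layered_sheet`,
  120 cells in $32^3$ voxels, 10 vs 10, $B = 200$, 20 master seeds; the
  median p-value falls below 0.05. At these sizes a run takes a few
  seconds per cohort pair; 120-cell samples are the smallest at which
  face-vector classes recur often enough for the proportion vectors of the
  two architectures to separate reliably.

## Morphometrics

The companion statistics operate on long-format per-cell tables (sample,
stage, tissue, cell id, volume in µm³), as exported by segmentation
attribute pipelines:

* `filter_small_cells()` removes segments below 30 µm³ — artifact size at
  this imaging scale; a cell exactly at the threshold is kept.
* `cvcv()` — coefficient of variation of cell volume, sample-sd ($n-1$)
  over mean by default (`"n"` available). Cells are pooled per
  (cohort, stage, tissue) by default; a per-sample mode averages per-sample
  CVs instead.
* `growth_table()` — stage-wise relative increase $[y(n+1) - y(n)]/y(n)$ of
  cohort means. Fixed (non-live) samples cannot be tracked through time, so
  growth is estimated from stage-wise cohort means; per-sample pairing is
  deliberately not attempted. Tissues missing at a stage yield flagged `NA`
  increments, never silent zeros.
* `tissue_proportions()` — per-sample tissue shares of total volume or cell
  count; shares sum to 1.
* `stage_threshold_extrapolation()` — transfers a staging lower limit
  between species by the min/max ratio of a reference species.
* `division_summary()` — totals and percentages of classified mitotic
  divisions (e.g. periclinal vs anticlinal); detection and orientation
  calling are upstream manual steps, only the tabulation is in scope.
  Percentages are kept raw and rounded (display parity).

## Numerical and degenerate-input conventions

* Cosphericality tolerance of the Delaunay oracle: $10^{-9}$ relative to
  the squared circumradius; violations raise an error naming the offending
  subset rather than guessing an orientation.
* Stage order is always declared (default: the 13-stage ovule series
  1-I … 3-VI); it is never inferred from string sort order.
* All generators are pure functions of an integer seed; master seeds derive
  child seeds for per-sample streams, and every result object records the
  seed it was computed with.
* Volumes round-trip bit-exactly through 16-bit multi-page TIFF; labels
  above 65535 are rejected rather than truncated.

## Known limitations

* The `block2` scheme reads corner contacts as adjacency; at voxel
  resolutions where real cell walls are thinner than a voxel this may
  overcount contacts. Use `pairwise_face` for a strict face-contact graph.
* Feature vectors discard all geometry (volume, shape, orientation); two
  architectures differing only metrically are invisible to the test.
* With very small nerves (tens of cells) face-vector classes rarely repeat
  and the test loses power; cohorts of at least ~100 cells per sample are
  recommended.
* HDF5 label volumes are not read; convert to multi-page TIFF.
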