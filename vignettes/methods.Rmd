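---
title: "Grid-based conservation prioritization from multi-tree phylogenetic diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based conservation prioritization from multi-tree phylogenetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloprior)
```

## The problem

Conservation planning traditionally ranks areas by species richness. Two
areas with the same species count can, however, hold very different amounts
of evolutionary history: ten close congeners carry far less unique branch
length than ten species scattered across a class. `phyloprior` implements a
grid-based prioritization that ranks cells by the evolutionary distinctness
of the species they contain, computed over a *collection* of independent
phylogenies — one per taxonomic group (a family, tribe or genus analysed
with its own tree) — together with georeferenced occurrence records.

The design target is an analysis of a tropical Andean-type region: many
groups, uncalibrated maximum-likelihood trees in substitution units,
occurrence data of very uneven density, a 0.25° analysis grid, and a
protected-area network covering roughly a tenth of the territory.

## Indices

For one tree and the species of one grid cell present on that tree:

* **AvTD** (average taxonomic distinctness, Δ⁺) is the mean patristic
  distance over all unordered pairs of present species. With fewer than two
  species the value is defined as 0 so that every cell is orderable.
* **PD** (Faith phylogenetic diversity) is the total branch length of the
  minimal subtree connecting the present species. The default is the
  unrooted variant — only edges lying on a path between two present tips
  count, so a single tip has PD 0; a rooted variant (adding the path to the
  root) is available as a switch.

Because the trees are independent and undated, no distance is defined
between species of different trees. Per-cell values are therefore computed
per tree and **summed** across trees (a mean-across-trees switch exists).
Summation is the only aggregation that stays consistent with later
accounting steps that sum AvTD over cells.

Distances are branch-length (patristic) by default. Because source trees
always carry optimized branch lengths here, this is the primary definition;
a unit-weight ("taxonomic steps") mode of `patristic()` supports the classic
distinctness variant for trees whose lengths are not trusted.

Both indices, the patristic matrix, and the shared-branch computations are
driven by a single tip×edge incidence structure of each rooted tree: an
edge lies on the i–j path iff exactly one of i, j descends from it; an edge
belongs to the spanning subtree of a set S iff some but not all of S
descends from it. This makes per-cell scoring a set of matrix products and
keeps a ~400-cell × 93-tree scoring run in seconds.

## Index selection

PD is, almost by construction, strongly coupled to richness; AvTD is not.
The package makes the choice explicit: both indices are standardized and
regressed on standardized richness over occupied cells with a Bayesian
simple linear regression, and the index with the smaller absolute posterior
mean slope is selected. The sampler is a small Gibbs scheme — conjugate
normal draws for intercept and slope (prior N(0, 10²)) and slice sampling
for the residual sd (half-Cauchy(1)) — whose contract is that with
standardized data the posterior mean slope sits within Monte-Carlo error
(±0.02 with 4,000 draws) of the closed-form OLS slope; the priors are
deliberately weak and the Bayesian machinery is retained for the posterior
itself, not for regularization.

`richness_decoupling()` exposes the same contrast without a map: subsets of
m species are drawn from the pooled species list (200 draws per m) and the
standardized expected index value is regressed on m. On generated data the
PD slope is near 1 while the AvTD slope is visibly smaller — the ordering,
not the absolute values, is the decision criterion.

## Prioritization, stability, clustering

Occupied cells are ranked and split into five rank quintiles Q1–Q5 of size
⌊n/5⌋ or ⌈n/5⌉ (ties broken by cell id — a stable, documented rule that
guarantees reproducibility on discrete-valued data; an empirical
value-breaks mode is a switch). Q5 is the priority class.

Robustness to the tree sample is probed by jackknife: subsets of the trees
(defaults mirroring a 93-tree design probed at 23, 46, 60 and 93 trees; 10
replicates each) are drawn without replacement, per-cell AvTD is recomputed
— per-tree contributions are cached, so a replicate is a row sum — and
cells reclassified. A cell's stay-probability is the fraction of replicates
keeping its full-data label, reported with an exact Clopper–Pearson 95%
interval (estimation, not testing). At the full subset size every replicate
reproduces the full-data labels exactly, which doubles as an internal
consistency check.

Cell similarity uses phylogenetic beta diversity, 1 − PhyloSor: shared
spanning branch length over the mean of the two cells' spanned lengths,
summed across trees. A cell spanning zero branch length (empty, unmatched,
or one species per tree) is treated as maximally dissimilar from any
spanning cell and identical to another such cell; these cells are logged.
The choice of PhyloSor is isolated in `beta_matrix()` so an alternative
(e.g. a UniFrac-type measure) is a drop-in. Cells are then partitioned
around medoids (PAM, deterministic BUILD + swap) into C1–C3, with the mean
silhouette width reported for k = 2…6 so the k = 3 choice is inspectable.

## Endemics and protected areas

A species is *endemic* here when the mean great-circle distance over all
unordered pairs of its occurrence points is strictly below 0.25° of arc
(~50 km near the equator): a point-like range at grid resolution. A
single-record species is endemic by convention; exact duplicate records are
collapsed first so the classification cannot depend on record multiplicity.
The all-pairs mean is one literal reading of "mean distance between
occurrences"; nearest-neighbour alternatives exist, and the choice is
confined to `classify_endemics()`. Haversine distance expressed in degrees
of arc is the default metric (the equator-adjacent study setting makes the
planar/great-circle difference negligible); a planar mode is available for
exact synthetic tests.

`endemic_impact()` removes endemic species — species-level removal, from
every cell at once — at fractions 25/50/75% (100 random replicates each;
rounding is half-up with a minimum of one species) and 100% (deterministic),
recomputing AvTD and the quintile labels each time. One subtlety: because
AvTD is a *mean*, removing a short-branch species can slightly *raise* a
cell's value, so the total percent change can be marginally negative; it is
reported as computed rather than clamped. The headline quantity is the
percent decrease of total AvTD at full removal, which on generated data is
far below the endemics' share of the species list — short pendant branches
buy little distinctness — alongside `branch_share`, the endemic fraction of
summed pendant branch length.

`pa_overlay()` marks a cell as protected when its rectangle intersects at
least one protected-area polygon with *positive area* — a boundary touch
does not count (a centroid-containment mode is the sensitivity switch).
Inside/outside sums of AvTD, PD and richness partition the grid totals
exactly; a cell under several polygons is counted once. Polygon–rectangle
intersection is computed by Sutherland–Hodgman clipping of each ring
followed by the shoelace formula, with holes subtracted; areas are in
square degrees and no equal-area reprojection is attempted (documented
limitation — at the near-equatorial latitudes targeted the distortion is
small).

## Sampling ignorance

Uneven survey effort is summarized per cell by the half-ignorance index
`O½ / (N + O½)` with N the cell's occurrence-record count: 1 for an
unsampled cell, 0.5 at N = O½ (default 10 records), decreasing toward 0.
Record counts, not distinct-species counts, are used — the per-cell record
total is what a single reliability raster can carry. The "high ignorance"
summary threshold defaults to 0.5 and is configurable.

## The synthetic generator

`synthetic_scenario()` fixes the study conditions; all randomness flows
from one seed through named per-stage substreams, so identical seed and
parameters give byte-identical files. The generator emulates:

* **Trees** — Yule topologies with iid exp(1) branch lengths: the simplest
  process giving heterogeneous patristic distances; no downstream
  computation depends on the generative process. Endemic tips get their
  pendant edge multiplied by `endemic_branch_scale` (default 0.1), coupling
  restricted range with short branches the way the motivating empirical
  pattern does.
* **Occurrences** — per species, a Gaussian cloud clipped (not resampled)
  to the domain, keeping clouds reproducible. Defaults: a 5°×5°
  near-equatorial domain (400 cells at 0.25°), 30–80 records per species,
  cloud sd 1°. These densities are chosen to emulate a *well-sampled*
  study region — several species and tens of records per cell — because
  that is the regime the analysis design assumes; they also keep a
  non-endemic's sample mean pairwise distance far above the endemism
  threshold, so planted endemics are recovered exactly. Endemic clouds use
  sd 0.25/(4√π) ≈ 0.035°, putting the *expected* mean pairwise distance
  near 0.063°, a quarter of the threshold.
* **Hotspots** — planted high-diversity cells receive the two
  longest-pendant non-endemic tips of *every* tree (two per tree, because a
  single tip per tree would contribute no pair and AvTD would stay 0).
* **Protected areas** — non-overlapping axis-aligned rectangles of equal
  area totalling `pa_coverage` (default 10%) of the domain, placed by
  rejection sampling; coverage above 0.9 is refused.

What the generator does **not** emulate: taxonomic error, spatial sampling
bias correlated with accessibility, coordinate noise, range shapes beyond
isotropic clouds, and real tree-shape imbalance. Passing tests therefore
demonstrate the pipeline's internal correctness and its behaviour under the
planted structure — not robustness to the messiness of real aggregated
occurrence data.

## Numerical choices and scale

Oracle comparisons in the test suite run at 1e-9; the positive-area rule
uses a 1e-12 area epsilon; beta dissimilarities are clipped into [0, 1]
against rounding. The test suite exercises the full pipeline at the
dimension of the motivating design — 93 trees and 1,252 species over a
400-cell grid, which completes in a few minutes on one CPU — while
unit-level checks use 6-tree scenarios over a 100-cell grid. Quantile
classification requires at least five occupied cells; clustering requires
k+1. Degenerate inputs (all-equal index values, zero-variance regressors,
empty cells, zero-length branches) are either handled by documented rules
or rejected with a named error.

## Known limitations

* Cross-tree distinctness is invisible by construction: two cells holding
  different *trees'* species entirely are simply unrelated in AvTD terms.
* Areas are degree-square; inside/outside accounting is exact, but area
  *fractions* ignore the cos(latitude) shrink of lon degrees.
* The endemism criterion is range-*spread*, not range-*size*; a species
  with two tight clusters 1° apart is "not endemic" under the all-pairs
  mean.
* The beta-diversity measure is fixed to 1 − PhyloSor; no abundance
  weighting anywhere (presence/absence throughout, by design).
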