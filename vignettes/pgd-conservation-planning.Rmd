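---
title: "Prioritizing landscapes with proxies of genetic differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing landscapes with proxies of genetic differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(pgdplan)
```

## The problem

Systematic conservation planning usually treats a species as a single
feature: a range map whose area should be represented inside a protected
network. That ignores intraspecific structure — populations in different
environments, or separated by long-standing geographic barriers, hold
differentiated genetic diversity, and a plan that captures 30% of a range
in one corner may capture none of that structure. When genomic data are
unavailable for most taxa (the normal situation for crop wild relatives and
most wild plants), a spatial surrogate is needed.

`pgdplan` implements such a surrogate — *proxies of genetic differentiation*
(PGD) — and the prioritization and evaluation machinery around it:

1. classify a climate stack into **Holdridge life zones** (environmental
   driver of differentiation);
2. subdivide each life zone by categorical cartography of historical
   isolation (biogeographic provinces, watersheds, edaphology) into
   non-overlapping PGD;
3. cross binarized species distribution models (SDM) with the PGD partition
   so each taxon × proxy piece becomes its own conservation feature;
4. rank the landscape by greedy **core-area zonation** (CAZ) removal under
   IUCN threat weights and habitat-condition layers;
5. evaluate representation of taxa and proxies along the ranking, and
   validate the proxy partition against genetic cluster memberships where
   genomic samples exist.

## Holdridge classification

Biotemperature is the annual mean of monthly mean temperatures after
clamping each month into [0, 30] °C — months outside that interval
contribute their clamped value, reflecting the temperature range in which
vegetative growth occurs. Annual potential evapotranspiration is
`58.93 mm × biotemperature`, and its ratio to annual precipitation indexes
aridity. Latitudinal belts cut biotemperature at
{1.5, 3, 6, 12, 24} °C and humidity provinces cut the PET ratio at
{0.125, 0.25, 0.5, 1, 2, 4, 8, 16, 32}, both log₂-spaced lattices.

Two conventions are fixed so boundary values classify deterministically:
belt intervals are lower-inclusive (a biotemperature of exactly 12 °C is
warm temperate), humidity intervals upper-exclusive. The frost-line
subdivision and the transitional triangles of the full Holdridge hexagon
chart are deliberately not used: the basic belt × humidity lattice is the
only deterministic, fully published reading, and the package's legend names
come from the packaged chart (`inst/extdata/holdridge_chart.csv`). A
consequence is that the number of distinct zones is data-dependent — the
classifier labels only occupied lattice cells, consecutively by
(belt, humidity).

```{r lifezones}
cfg <- sim_config(seed = 1, n_rows = 40, n_cols = 40)
land <- simulate_landscape(cfg)
lz <- classify_lifezones(land$climate)
glance(lz)
```

## From life zones to proxies of genetic differentiation

Which cartography best explains isolation differs among life zones, and in
real use that choice is expert input from a phylogeographic literature
review. The package therefore takes the choice as data: an assignment table
mapping each life-zone id to an ordered list of divider rasters (possibly
empty = no subdivision). Within a zone, cells are partitioned by the joint
divider class; every occupied combination becomes a PGD, labeled
consecutively by (zone id, class tuple) so identical inputs always yield
identical maps. PGD need not be spatially connected — a proxy may consist
of several patches, exactly like a life-zone fragment split by a province
border. A divider label of 0 under a land cell is kept as an
"unclassified" class rather than dropped, preserving the partition
invariant (the PGD map refines the life-zone map and conserves the land
mask cell count).

Sliver handling is optional and off by default (`filter_fragments()`,
`min_cells = 0`): nothing in the method requires a minimum proxy area, so
merging is a user decision. When enabled, fragments are absorbed into their
largest rook-adjacent proxy *of the same life zone* — merging across zones
would break the nesting invariant — and isolated fragments drop to nodata
with a log entry.

```{r pgd}
ds <- divider_set(land$dividers, cycled_assignment(lz, names(land$dividers)))
pgd <- subdivide_lifezones(lz, ds)
glance(pgd)
```

## Conservation features

**Binarization.** Continuous suitability surfaces are cut at an order
statistic of the suitabilities observed at the training presences: the
minimum (`mtp`) or the ten-percentile threshold (`p10`), implemented as the
k-th smallest presence suitability with `k = ceiling(0.1 n)`. The ceiling
rule is one concrete choice among the interpolation conventions in use;
it is lower-value-inclusive, so `p10` is never below `mtp`.

**Intersection.** Crossing every taxon with every proxy produces
`n_taxa × n_pgd` candidate layers; empty overlaps are dropped and the kept
layers per taxon partition the taxon's distribution on the land mask. Binary
features carry value 1 per occupied cell, so represented value equals
represented area.

**Weights.** IUCN threat categories map to ranking weights
(CR 1, EN 1, VU 0.8, NT 0.5, DD 0.3, LC 0.2, NE 0.1); occurrence-only
taxa (SSI, species of special interest) are always weighted 1, since their
few known localities are irreplaceable. An explicit weight of 0 excludes a
feature from the ranking while keeping it for evaluation.

**Habitat condition.** Land cover is aggregated to seven categories;
rainfed/moisture agriculture is split into less-intensive versus intensive
by administrative-unit average maize yield at an inclusive 3 t/ha boundary
(the yield level below which traditional, landrace-compatible agriculture
predominates). Each taxon's expert habitat preferences (1 / 0.5 / 0.1 per
category) become a per-taxon multiplier raster applied to its feature
values during ranking. Point (SSI) features are never condition-linked: a
known occurrence is evidence of presence regardless of mapped land cover.
Cells with no land-cover information leave feature values unchanged
(multiplier 1) rather than zeroing them.

## Core-area zonation ranking

At each step the cell with the smallest marginal loss

$$\delta_i = \max_j \frac{w_j\, v'_{ij}}{Q_j}$$

is removed, where $v'_{ij}$ is feature $j$'s (condition-weighted) value in
cell $i$, $Q_j$ its remaining total over retained cells, and $w_j$ its
weight. The max makes the rule conservative: a cell is expensive if it is
important for *any* feature relative to what that feature has left, so
range-restricted features retain their core areas into the top fractions.
Cell cost is uniform — no cost layer enters the analysis — and exhausted
features ($Q_j = 0$) are skipped.

Numerical choices, all exposed in `rank_config()`:

* **Ties** in $\delta$ break by lowest linear cell index by default
  (bit-reproducible runs); a seeded random tie-break is available.
* **warp** removes that many cells per recomputation batch. `warp = 1` is
  the exact greedy; larger values trade within-batch ordering for speed,
  leaving representation at batch boundaries unchanged up to batch-size
  quantization.
* **Edge-only removal** (an approximation device in some ranking software)
  is not used: every retained cell is a removal candidate at every step.
* Remaining totals are updated by subtraction; features are considered
  exhausted below 1e-12 to keep the division stable.

Ranks are removal order divided by the number of land cells, a permutation
of {1/N, …, 1}; `top_fraction(rank, f)` thresholds at `1 − f`, and masks
nest along f by construction.

**Planning units (ADMU).** `admu_rank()` runs the same greedy
independently inside each proxy and interleaves units by within-unit rank
quantile (ties across units by unit id), so each unit contributes ≈ f of
its own area at every top fraction. This quantile interleave is this
package's concrete reading of the administrative-units mode of the Zonation
software family, whose internal unit weighting is not published in a form
that can be reimplemented exactly; the construction here makes the
guarantee it is used for — representation inside every unit — exact up to
one-cell quantization.

```{r rank}
sim <- simulate_taxa(cfg, pgd)
sdm <- lapply(setNames(names(sim$suitability), names(sim$suitability)),
              function(tx) {
  pts <- points_to_cells(sim$presences[[tx]], pgd$zones$spec)
  binarize_sdm(sim$suitability[[tx]], pts, "p10")$grid
})
fs <- build_scenario("SDMxPGD", sdm, pgd = pgd)
rk <- caz_rank(fs, mask = pgd$zones)
glance(rk)
```

## Evaluation

Representation curves report, per feature, the retained proportion of its
total value as a function of the top landscape fraction; they are exact
step functions computed from the removal order, left-continuous on the
rank lattice (the value at `f` counts cells with rank `> 1 − f`).
"Area represented" is computed on binary occupancy; condition-weighted
variants are reported separately when conditions were applied, keeping the
two readings auditable. Per-taxon summaries average a taxon's non-empty
zone-layers without weighting — the simplest defensible reduction, flagged
as such since other reductions (area-weighted means) are possible.

Genetic validation assigns each sampling locality to the proxy most
frequent among cell centres within a buffer radius (5 km on a metric 1-km
grid; cell-centre inclusion, no partial-cell weighting; ties to the
smallest proxy id; radius 0 degenerates to the containing cell), reduces
admixture membership vectors to their dominant cluster (ties to the
smallest index), and summarizes agreement between the cluster and proxy
partitions with the adjusted Rand index computed by its standard
closed form from the contingency table. The index adds a quantitative
summary to what is otherwise a visual comparison of admixture bar plots
against zone assignments.

```{r evaluate}
curves <- representation_curves(rk, fs)
head(mean_curve(curves, at = c(0.1, 0.2, 0.3)))
```

## What the synthetic generator emulates — and what it does not

`simulate_landscape()` builds monthly temperatures as a smooth north-south
gradient plus seeded spatially correlated noise (white noise smoothed with
a separable Gaussian kernel — the simplest controllable autocorrelation),
precipitation as an independent west-east gradient, dividers as Voronoi
partitions, a seven-category land-cover mosaic, and administrative-unit
yields drawn around the 3 t/ha boundary. `simulate_taxa()` seeds each
taxon's suitability as a Gaussian-kernel mixture inside a random subset of
proxies (so ranges are nested in the partition, with presences sampled
proportional to suitability, ≥ 20 per modeled taxon), and
`simulate_genetics()` draws admixture memberships from a Dirichlet
concentrated on the home proxy's cluster — `alpha → ∞` gives pure
memberships, `alpha = 1` a structure-free draw.

Defaults (60 × 60 cells of 1 km; 8 modeled + 2 SSI taxa; 30 presences;
2 dividers with 3 and 4 classes; 200 samples; `alpha = 50`) were chosen
once as a plausible desk-scale analogue of a national analysis; test
worlds use 20–30 cells a side so the exact greedy stays fast. What passing
tests show is that the *machinery* is correct — partitions partition,
greedy equals oracle, curves are monotone, limits behave. What they cannot
show is realism: real climates have topography and covariance between
temperature and rainfall, real cartography has slivers and digitizing
artifacts, real SDMs have spatial bias and truncation, and real admixture
has isolation-by-distance gradients rather than clean cluster-per-proxy
structure. Results on synthetic worlds bound what the method can do under
its own assumptions, not what it will find in any particular country.

## Degenerate inputs and edge behaviour

* Misaligned rasters are a hard error naming the offending field — the
  package never resamples.
* Zero precipitation on a data cell is an error (the PET ratio is
  undefined), listing cell indices.
* Points outside the grid are flagged, never dropped; buffer neighbourhoods
  with no labelled cell leave a sample unassigned, and unassigned samples
  are excluded from the crosstab with their count reported.
* A feature with zero total is reported as undefined (`NA`) in curves, not
  silently 0; all-empty feature sets refuse to rank.
* Degenerate contingency tables (single cluster or single zone) return an
  adjusted Rand index of 0, the chance-level value.

## Known limitations

* The raster container is deliberately minimal: single-band, planar,
  equal-area square cells, ESRI ASCII on disk. Reprojection, resampling and
  multi-resolution inputs are out of scope; inputs must arrive on one
  analysis grid.
* The greedy ranking is exact but O(removals × dirty-cell updates) in pure
  R; national-scale grids (10⁶ cells) would need the `warp` batching and
  patience, or a compiled core.
* The quantile-interleave ADMU mode and the unweighted per-taxon mean are
  single concrete readings of ambiguous descriptions; both are isolated
  behind their function boundaries so alternative readings can be swapped
  in.
* The expert steps — divider choice per life zone, habitat preference
  scores, removal of overestimated SDM areas — enter as data, not as
  computation.
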