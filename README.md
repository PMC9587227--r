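# pgdplan

Spatial conservation prioritization that carries **intraspecific genetic
differentiation** into the plan — without genomic data for every taxon.

Most planning exercises treat a species as one feature: a range whose area
should be represented in the selected network. But populations in different
environments, or separated by long-standing barriers, hold differentiated
genetic diversity, and a plan can "represent" a species while missing all
of that structure. For taxa where genomes are unsequenced (the usual case
for crop wild relatives), `pgdplan` builds spatially explicit **proxies of
genetic differentiation (PGD)**: Holdridge life zones (the environmental
driver of differentiation) subdivided by cartography of historical
isolation — biogeographic provinces, watersheds, edaphology. Each taxon ×
PGD overlap then enters the prioritization as its own conservation
feature, so the plan must represent every potentially differentiated
population, not just the range total.

## What it computes

* **Holdridge life zones** from a monthly-temperature + annual-precipitation
  stack. Biotemperature is the mean of monthly temperatures clamped to
  [0, 30] °C; potential evapotranspiration is 58.93 mm per °C of
  biotemperature; belts cut biotemperature at {1.5, 3, 6, 12, 24} °C and
  humidity provinces cut the PET ratio at {0.125, …, 32} (log₂ lattice).
* **PGD maps**: each life zone partitioned by the joint class of its
  assigned divider rasters; occupied combinations relabeled consecutively;
  the result refines the life-zone partition and conserves the land mask.
* **Feature stacks**: SDM binarization at presence order statistics
  (minimum training presence, or the ten-percentile rule
  `k = ceiling(0.1 n)`); taxon × PGD intersections; IUCN threat weights
  (CR 1, EN 1, VU 0.8, NT 0.5, DD 0.3, LC 0.2, NE 0.1); per-taxon
  habitat-condition rasters from expert preference scores (1 / 0.5 / 0.1)
  over seven land-cover categories, with agriculture split at an inclusive
  3 t/ha yield boundary; occurrence-only (SSI) taxa as point features.
* **Core-area zonation (CAZ) ranking**: iteratively remove the cell with
  the smallest marginal loss
  `delta_i = max_j w_j v'_ij / Q_j`
  (`v'` condition-weighted value, `Q_j` the feature's remaining total,
  `w_j` its weight), producing a hierarchical priority rank map whose top
  fractions nest. A planning-unit variant (`admu_rank()`) guarantees every
  PGD contributes ≈ f of its own area at every top fraction f.
* **Evaluation**: per-feature representation curves, per-taxon mean PGD
  representation, per-PGD retention at an area threshold, overlay
  statistics against reference layers, and validation of the PGD partition
  against admixture cluster memberships (buffer-majority assignment of
  sampling localities, adjusted Rand index of the cluster × proxy
  crosstab).
* **Synthetic landscapes** (`sim_config()`, `simulate_landscape()`,
  `simulate_taxa()`, `simulate_genetics()`): seeded, reproducible worlds
  with climate gradients, Voronoi cartography, kernel-mixture ranges and
  cluster-per-PGD admixture structure, so the whole pipeline is testable
  offline.

Rasters are read and written as plain-text ESRI ASCII grids
(`read_grid()` / `write_grid()`); all inputs must share one analysis grid —
the package never resamples.

## Worked example

```r
library(pgdplan)

cfg  <- sim_config(seed = 1, n_rows = 40, n_cols = 40)
land <- simulate_landscape(cfg)
lz   <- classify_lifezones(land$climate)
glance(lz)
#> # A tibble: 1 × 4
#>   n_zones n_cells n_belts n_humidity
#> 1      20    1600       5         10

pgd <- subdivide_lifezones(
  lz, divider_set(land$dividers, cycled_assignment(lz, names(land$dividers))))
glance(pgd)
#> # A tibble: 1 × 4
#>   n_pgd n_zones n_cells median_cells
#> 1    37      20    1600           21

sim <- simulate_taxa(cfg, pgd)
sdm <- lapply(setNames(nm = names(sim$suitability)), function(tx) {
  pts <- points_to_cells(sim$presences[[tx]], pgd$zones$spec)
  binarize_sdm(sim$suitability[[tx]], pts, "p10")$grid
})

fs <- build_scenario("SDMxPGD", sdm, pgd = pgd)
#> <feature_set> scenario 'SDMxPGD', 9 features on 40x40 @ 1000
rk <- caz_rank(fs, mask = pgd$zones)

curves <- representation_curves(rk, fs)
mean_curve(curves, at = c(0.1, 0.2, 0.3))
#> # A tibble: 3 × 2
#>       f mean_rep
#> 1   0.1    0.525
#> 2   0.2    0.782
#> 3   0.3    0.921

head(pgd_area_representation(top_fraction(rk, 0.2), sdm[["taxon_01"]], pgd), 1)
#> # A tibble: 1 × 4
#>   pgd_id n_cells n_retained proportion
#> 1     15      73         54      0.740
```

Reading: the 40 × 40 synthetic landscape splits into 20 life zones and 37
PGD. The eight simulated taxa intersect the proxies in 9 non-empty
taxon × PGD features; ranking the 1600 land cells by CAZ and keeping the
top 20% retains on average 78% of each feature's distribution — and 74% of
taxon_01's range piece inside proxy 15, the kind of per-population
guarantee that motivates subdividing ranges in the first place.
`autoplot()` methods exist for every result object (`autoplot(rk)`,
`autoplot(curves)`, …), and `tidy()`/`glance()` return tibbles throughout.

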