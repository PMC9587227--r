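# Shared fixtures: tiny grids and feature sets built in code.

toy_spec <- function(nr = 2, nc = 2, cs = 1000) {
  grid_spec(nr, nc, origin_x = 0, origin_y = nr * cs, cell_size = cs,
            crs_id = "toy")
}

# constant monthly temperature stack
constant_climate <- function(temp, precip, nr = 3, nc = 3) {
  sp <- toy_spec(nr, nc)
  climate_stack(
    lapply(1:12, function(m) value_grid(sp, matrix(temp, nr, nc))),
    value_grid(sp, matrix(precip, nr, nc))
  )
}

# feature set from dense per-feature value matrices (list of nr x nc matrices)
dense_feature_set <- function(mats, spec, weights = NULL, taxa = NULL,
                              pgd_ids = NULL) {
  feats <- lapply(seq_along(mats), function(j) {
    v <- as.vector(mats[[j]])
    cells <- which(v > 0)
    pgdplan:::new_feature_layer(
      feature_id = names(mats)[j] %||% paste0("f", j),
      taxon = if (is.null(taxa)) NA_character_ else taxa[j],
      pgd_id = if (is.null(pgd_ids)) 0L else pgd_ids[j],
      kind = "raster", cells = cells, values = v[cells],
      weight = if (is.null(weights)) 1 else weights[j]
    )
  })
  pgdplan:::new_feature_set(feats, spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small end-to-end synthetic world shared by several test files
make_world <- function(seed = 42, n_rows = 30, n_cols = 30, n_taxa = 5,
                       n_ssi = 1, ...) {
  cfg <- sim_config(seed = seed, n_rows = n_rows, n_cols = n_cols,
                    n_taxa = n_taxa, n_ssi = n_ssi, ...)
  land <- simulate_landscape(cfg)
  lz <- classify_lifezones(land$climate)
  ds <- divider_set(land$dividers, cycled_assignment(lz, names(land$dividers)))
  pgd <- subdivide_lifezones(lz, ds)
  taxa_sim <- simulate_taxa(cfg, pgd)
  list(cfg = cfg, land = land, lz = lz, pgd = pgd, taxa = taxa_sim)
}

# binarize all simulated taxa at p10
binarize_world <- function(world) {
  sdm <- list()
  for (tx in names(world$taxa$suitability)) {
    pts <- points_to_cells(world$taxa$presences[[tx]],
                           world$pgd$zones$spec)
    sdm[[tx]] <- binarize_sdm(world$taxa$suitability[[tx]], pts, "p10")$grid
  }
  sdm
}
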