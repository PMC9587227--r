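test_that("identical seeds reproduce the landscape bit-for-bit; seeds differ otherwise", {
  cfg <- sim_config(seed = 7, n_rows = 15, n_cols = 15)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$climate$annual_precipitation$values,
                   b$climate$annual_precipitation$values)
  expect_identical(a$landcover$labels, b$landcover$labels)
  expect_identical(a$yields, b$yields)
  c <- simulate_landscape(sim_config(seed = 8, n_rows = 15, n_cols = 15))
  expect_false(identical(a$climate$annual_precipitation$values,
                         c$climate$annual_precipitation$values))
})

test_that("divider class counts follow the configuration", {
  cfg <- sim_config(seed = 3, n_rows = 20, n_cols = 20,
                    divider_classes = c(3L, 4L))
  land <- simulate_landscape(cfg)
  expect_named(land$dividers, c("divider1", "divider2"))
  expect_lte(dplyr::n_distinct(as.vector(land$dividers$divider1$labels)), 3)
  expect_lte(dplyr::n_distinct(as.vector(land$dividers$divider2$labels)), 4)
  # Voronoi seeds at this density occupy every class
  expect_equal(sort(unique(as.vector(land$dividers$divider1$labels))), 1:3)
})

test_that("land-cover uses only pre-split categories and yields straddle 3 t/ha", {
  land <- simulate_landscape(sim_config(seed = 19, n_rows = 25, n_cols = 25))
  expect_true(all(land$landcover$labels %in% c(1L, 2L, 3L, 5L, 6L, 7L)))
  expect_true(any(land$yields$yield_t_ha <= 3) && any(land$yields$yield_t_ha > 3))
  split <- intensity_split(land$landcover, land$admin_units, land$yields)
  expect_true(all(split$labels %in% 1:7))
})

test_that("simulated taxa have presences inside their suitability support", {
  world <- make_world(seed = 37, n_rows = 20, n_cols = 20, n_taxa = 4, n_ssi = 2)
  sim <- world$taxa
  expect_equal(length(sim$suitability), 4)
  expect_equal(length(sim$presences), 6) # modeled + SSI occurrences
  expect_equal(sum(!sim$taxa$has_sdm), 2)
  for (tx in names(sim$suitability)) {
    pts <- points_to_cells(sim$presences[[tx]], world$pgd$zones$spec)
    s <- as.vector(sim$suitability[[tx]]$values)[pts$cell]
    expect_true(all(!is.na(s) & s > 0)) # support containment
    expect_gte(nrow(sim$presences[[tx]]), 20)
  }
  expect_true(all(sim$taxa$iucn %in% names(iucn_weights())))
  prefs <- as.matrix(sim$taxa[paste0("pref_", 1:7)])
  expect_true(all(prefs %in% c(1, 0.5, 0.1)))
})

test_that("a taxon seeded in a single PGD keeps all presences in that PGD", {
  world <- make_world(seed = 51, n_rows = 20, n_cols = 20, n_taxa = 6,
                      pgds_per_taxon = 1)
  zl <- world$pgd$zones$labels
  for (tx in names(world$taxa$suitability)) {
    pts <- points_to_cells(world$taxa$presences[[tx]], world$pgd$zones$spec)
    expect_equal(dplyr::n_distinct(zl[cbind(pts$row, pts$col)]), 1)
  }
})

test_that("presence density increases with suitability (rank correlation)", {
  world <- make_world(seed = 61, n_rows = 25, n_cols = 25, n_taxa = 3,
                      n_presences = 1000)
  for (tx in names(world$taxa$suitability)) {
    pts <- points_to_cells(world$taxa$presences[[tx]], world$pgd$zones$spec)
    counts <- table(pts$cell)
    suit <- as.vector(world$taxa$suitability[[tx]]$values)
    support <- which(!is.na(suit) & suit > 0)
    dens <- numeric(length(support))
    dens[match(as.integer(names(counts)), support)] <- counts
    expect_gt(suppressWarnings(
      cor(suit[support], dens, method = "spearman")), 0)
  }
})

test_that("membership vectors are simplex-valued and track alpha limits", {
  world <- make_world(seed = 71, n_rows = 20, n_cols = 20, n_taxa = 3)
  # a land-wide distribution so samples span many proxies
  sdm <- value_grid(world$pgd$zones$spec,
                    matrix(as.numeric(world$pgd$zones$labels > 0L), 20, 20))

  pure_cfg <- sim_config(seed = 71, n_rows = 20, n_cols = 20, alpha = 1e8,
                         n_samples = 150)
  pure <- simulate_genetics(pure_cfg, world$pgd, sdm)
  expect_equal(rowSums(as.matrix(pure[grep("^cluster_", names(pure))])),
               rep(1, 150), tolerance = 1e-9)
  assigned <- assign_samples_to_pgd(pure, world$pgd, radius = 0)
  ct <- cluster_zone_crosstab(assigned)
  expect_equal(ct$ari, 1) # pure memberships recover the zone partition

  # identical seed reproduces the table
  pure2 <- simulate_genetics(pure_cfg, world$pgd, sdm)
  expect_identical(pure, pure2)

  expect_error(
    simulate_genetics(pure_cfg, world$pgd,
                      value_grid(world$pgd$zones$spec,
                                 matrix(0, 20, 20))),
    class = "pgdplan_error_synthetic"
  )
})

test_that("flat admixture (alpha = 1) shows no zone structure across 10 seeds", {
  world <- make_world(seed = 81, n_rows = 20, n_cols = 20, n_taxa = 3)
  sdm <- value_grid(world$pgd$zones$spec,
                    matrix(as.numeric(world$pgd$zones$labels > 0L), 20, 20))
  aris <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 100 + s, n_rows = 20, n_cols = 20, alpha = 1,
                      n_samples = 500)
    g <- simulate_genetics(cfg, world$pgd, sdm)
    cluster_zone_crosstab(assign_samples_to_pgd(g, world$pgd, 0))$ari
  }, numeric(1))
  expect_true(all(abs(aris) < 0.1))
})

test_that("the full pipeline runs end-to-end and satisfies curve invariants", {
  world <- make_world(seed = 91, n_rows = 30, n_cols = 30, n_taxa = 6, n_ssi = 1)
  sdm <- binarize_world(world)[sprintf("taxon_%02d", 1:6)]
  split_lc <- intensity_split(world$land$landcover, world$land$admin_units,
                              world$land$yields)
  taxa <- assign_weights(world$taxa$taxa, ssi_ids = "ssi_01")
  conditions <- lapply(setNames(names(sdm), names(sdm)), function(tx) {
    prefs <- as.numeric(taxa[taxa$taxon == tx, paste0("pref_", 1:7)])
    habitat_condition(split_lc, prefs)
  })
  fs <- build_scenario("SDMxPGD", sdm, pgd = world$pgd,
                       ssi_points = world$taxa$presences["ssi_01"],
                       weights = setNames(taxa$weight, taxa$taxon),
                       conditions = TRUE)
  rk <- caz_rank(fs, conditions = conditions)
  expect_equal(rk$n_land, length(unique(unlist(
    lapply(fs$features, function(f) f$cells)))))
  curves <- representation_curves(rk, fs, conditions = conditions)
  ok <- curves[!is.na(curves$rep), ]
  for (fid in unique(ok$feature_id)) {
    cc <- ok[ok$feature_id == fid, ]
    expect_equal(cc$rep[cc$f == 0], 0)
    expect_equal(cc$rep[cc$f == 1], 1)
    expect_true(all(diff(cc$rep[order(cc$f)]) >= -1e-12))
  }
})
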