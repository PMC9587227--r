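test_that("representation curves hit the worked-example value and obey endpoints", {
  sp <- toy_spec(2, 2)
  fs <- dense_feature_set(
    list(A = matrix(c(3, 1, 0, 0), 2, 2), B = matrix(c(0, 0, 2, 2), 2, 2)),
    sp
  )
  rk <- caz_rank(fs)
  curves <- representation_curves(rk, fs)
  A <- curves[curves$feature_id == "A", ]
  # top half retains {cell 1, cell 4}: A keeps 3 of 4
  expect_equal(A$rep[abs(A$f - 0.5) < 1e-9], 3 / 4)
  for (fid in c("A", "B")) {
    cc <- curves[curves$feature_id == fid, ]
    expect_equal(cc$rep[cc$f == 0], 0)
    expect_equal(cc$rep[cc$f == 1], 1)
    expect_true(all(diff(cc$rep[order(cc$f)]) >= -1e-12))
  }
})

test_that("zero-total features are reported as undefined, not silently zero", {
  sp <- toy_spec(2, 2)
  fs <- dense_feature_set(list(a = matrix(c(1, 1, 0, 0), 2, 2)), sp)
  # append an evaluation-only feature with zero total value
  fs$features[[2]] <- pgdplan:::new_feature_layer(
    "empty", NA_character_, 0L, "raster", integer(0), numeric(0), weight = 0
  )
  rk <- caz_rank(fs)
  curves <- representation_curves(rk, fs)
  expect_true(all(is.na(curves$rep[curves$feature_id == "empty"])))
  expect_false(anyNA(curves$rep[curves$feature_id == "a"]))
})

test_that("per-taxon mean PGD representation averages zone-layers (mask oracle)", {
  sp <- toy_spec(2, 2)
  # taxon t with two zone-layers: rep 0.2 vs 0.8 is emulated by retention
  fs <- dense_feature_set(
    list(A = matrix(c(3, 1, 0, 0), 2, 2), B = matrix(c(0, 0, 2, 2), 2, 2)),
    sp, taxa = c("t", "t"), pgd_ids = c(1L, 2L)
  )
  rk <- caz_rank(fs)
  curves <- representation_curves(rk, fs)
  out <- taxon_mean_pgd_representation(curves, fs, f = 0.5)
  expect_equal(out$taxon, "t")
  expect_equal(out$n_layers, 2L)
  expect_equal(out$mean_rep, (3 / 4 + 2 / 4) / 2) # arithmetic mean of layers

  # single-layer taxon returns that layer's value; full retention -> 1
  out1 <- taxon_mean_pgd_representation(curves, fs, f = 1)
  expect_equal(out1$mean_rep, 1)

  # IUCN grouping joins through
  taxa <- tibble::tibble(taxon = "t", iucn = "EN")
  expect_equal(taxon_mean_pgd_representation(curves, fs, 0.5, taxa)$iucn, "EN")
})

test_that("taxon means recomputed from curves equal direct mask counting", {
  world <- make_world(seed = 29, n_rows = 20, n_cols = 20, n_taxa = 5)
  sdm <- binarize_world(world)[sprintf("taxon_%02d", 1:5)]
  fs <- build_scenario("SDMxPGD", sdm, pgd = world$pgd)
  rk <- caz_rank(fs)
  curves <- representation_curves(rk, fs)
  f <- 0.2
  from_curves <- taxon_mean_pgd_representation(curves, fs, f)
  mask <- top_fraction(rk, f)
  for (tx in from_curves$taxon) {
    per_layer <- pgd_area_representation(mask, sdm[[tx]], world$pgd)
    expect_equal(from_curves$mean_rep[from_curves$taxon == tx],
                 mean(per_layer$proportion))
  }
})

test_that("per-PGD representation counts cells exactly", {
  sp <- toy_spec(2, 3)
  pgd <- as_pgd_map(label_grid(sp, matrix(c(1L, 1L, 1L, 1L, 2L, 2L), 2, 3)))
  sdm <- value_grid(sp, matrix(c(1, 1, 1, 1, 1, 1), 2, 3))
  mask <- label_grid(sp, matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 2, 3))
  out <- pgd_area_representation(mask, sdm, pgd)
  # pgd 1: 4 distribution cells, 2 retained; pgd 2: 2 cells, 2 retained
  expect_equal(out$proportion, c(0.5, 1.0))

  full <- label_grid(sp, matrix(1L, 2, 3))
  expect_equal(pgd_area_representation(full, sdm, pgd)$proportion, c(1, 1))
  none <- label_grid(sp, matrix(0L, 2, 3))
  expect_equal(pgd_area_representation(none, sdm, pgd)$proportion, c(0, 0))
  # PGDs with no overlap are omitted
  sdm2 <- value_grid(sp, matrix(c(1, 1, 0, 0, 0, 0), 2, 3))
  expect_equal(pgd_area_representation(mask, sdm2, pgd)$pgd_id, 1L)
})

test_that("overlay statistics are exact mask proportions", {
  sp <- toy_spec(2, 5)
  mask <- label_grid(sp, matrix(c(rep(1L, 10)), 2, 5))
  inside3 <- label_grid(sp, matrix(c(1L, 1L, 1L, rep(0L, 7)), 2, 5))
  out <- overlay_stats(mask, list(pa = inside3, all = mask,
                                  none = label_grid(sp, matrix(0L, 2, 5))))
  expect_equal(out$proportion, c(0.3, 1, 0))
  expect_equal(unique(out$n_mask), 10L)
  empty <- label_grid(sp, matrix(0L, 2, 5))
  expect_error(overlay_stats(empty, list(pa = inside3)),
               class = "pgdplan_error_evaluate")
})

test_that("buffer assignment takes the majority label with smallest-id ties", {
  sp <- grid_spec(5, 5, origin_x = 0, origin_y = 5000, cell_size = 1000)
  # left 3 columns zone 7, right 2 columns zone 9
  lab <- matrix(rep(c(7L, 7L, 7L, 9L, 9L), each = 5), 5, 5)
  pgd <- as_pgd_map(label_grid(sp, lab))
  prov <- pgd$provenance # relabeled 1 (zone 7) and 2 (zone 9)
  deep <- tibble::tibble(x = 500, y = 2500)
  expect_equal(assign_samples_to_pgd(deep, pgd, 1000)$pgd_id, 1L)

  # boundary point: buffer of radius 2000 centred near the divide
  boundary <- tibble::tibble(x = 3000, y = 2500)
  out <- assign_samples_to_pgd(boundary, pgd, 2000)
  # count cell centres within 2000 m on each side: the majority wins
  centres <- expand.grid(r = 1:5, c = 1:5)
  cx <- (centres$c - 0.5) * 1000
  cy <- 5000 - (centres$r - 0.5) * 1000
  d <- sqrt((cx - 3000)^2 + (cy - 2500)^2)
  counts <- table(lab[cbind(centres$r, centres$c)][d <= 2000])
  expect_equal(out$pgd_id,
               unname(prov$pgd_id[match(as.integer(names(which.max(counts))),
                                        prov$zone_id)]))

  # radius 0 degenerates to the containing cell
  expect_equal(assign_samples_to_pgd(tibble::tibble(x = 4500, y = 500),
                                     pgd, 0)$pgd_id, 2L)

  # exact tie between two labels goes to the smallest id
  half <- matrix(rep(c(3L, 8L), each = 10), 5, 4)
  sp2 <- grid_spec(5, 4, origin_x = 0, origin_y = 5000, cell_size = 1000)
  pgd2 <- as_pgd_map(label_grid(sp2, half))
  tie <- tibble::tibble(x = 2000, y = 2500) # symmetric around the divide
  expect_equal(assign_samples_to_pgd(tie, pgd2, 1600)$pgd_id, 1L)

  expect_error(assign_samples_to_pgd(tibble::tibble(x = Inf, y = 0), pgd, 10),
               class = "pgdplan_error_points")
})

test_that("adjusted Rand index matches pair counting and independent references", {
  # perfect agreement
  expect_equal(adjusted_rand_index(diag(c(5, 3, 4))), 1)
  # one cluster against several zones is chance-level
  expect_equal(adjusted_rand_index(matrix(c(4, 5, 6), 1, 3)), 0)
  withr::with_seed(55, {
    for (i in 1:10) {
      a <- sample(1:3, 40, replace = TRUE)
      b <- sample(1:4, 40, replace = TRUE)
      tab <- table(a, b)
      expect_equal(adjusted_rand_index(tab), oracle_ari(a, b))
      expect_equal(adjusted_rand_index(tab),
                   mclust::adjustedRandIndex(a, b))
    }
  })
})

test_that("cluster-zone crosstab reduces memberships to dominant clusters", {
  samples <- tibble::tibble(
    pgd_id = c(1L, 1L, 2L, 2L, NA),
    cluster_1 = c(0.9, 0.6, 0.1, 0.5, 0.3),
    cluster_2 = c(0.1, 0.4, 0.9, 0.5, 0.7)
  )
  out <- cluster_zone_crosstab(samples)
  expect_equal(out$n_used, 4)
  expect_equal(out$n_unassigned, 1)
  expect_equal(sum(out$table), 4)
  # row 4 ties 0.5/0.5 -> smallest cluster index (1)
  expect_equal(unname(out$table["1", "2"]), 1)
  expect_equal(out$ari, adjusted_rand_index(out$table))
  expect_error(cluster_zone_crosstab(tibble::tibble(pgd_id = 1)),
               class = "pgdplan_error_evaluate")
  bad <- tibble::tibble(pgd_id = 1L, cluster_1 = 0.4, cluster_2 = 0.4)
  expect_error(cluster_zone_crosstab(bad), class = "pgdplan_error_evaluate")
})
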