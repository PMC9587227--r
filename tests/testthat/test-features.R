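test_that("binarization thresholds match a sorting oracle", {
  sp <- toy_spec(4, 5)
  suit <- value_grid(sp, matrix(seq(0.05, 1, by = 0.05), 4, 5))
  cells <- 1:20 # presences at every cell, suitabilities 0.05..1.00
  p10 <- binarize_sdm(suit, cells, "p10")
  expect_equal(p10$threshold, 0.10) # k = ceil(0.1 * 20) = 2 -> 2nd smallest
  expect_equal(sum(p10$grid$values), sum(suit$values >= 0.10))

  mtp <- binarize_sdm(suit, which(as.vector(suit$values) %in% c(0.3, 0.7)), "mtp")
  expect_equal(mtp$threshold, 0.3)
  expect_true(all(p10$grid$values %in% 0:1))
  expect_equal(as.vector(mtp$grid$values), as.numeric(as.vector(suit$values) >= 0.3))

  # identical presence suitabilities: both rules give that value
  suit2 <- value_grid(sp, matrix(0.4, 4, 5))
  expect_equal(binarize_sdm(suit2, 1:5, "p10")$threshold, 0.4)
  expect_equal(binarize_sdm(suit2, 1:5, "mtp")$threshold, 0.4)

  # all presences on nodata is an error
  suit3 <- value_grid(sp, matrix(NA_real_, 4, 5))
  expect_error(binarize_sdm(suit3, 1:3, "p10"), class = "pgdplan_error_features")
})

test_that("p10/mtp order statistics match the oracle on 100 random presence sets", {
  withr::with_seed(21, {
    for (i in 1:100) {
      n <- sample(5:60, 1)
      s <- round(runif(n), 3)
      sp <- grid_spec(1, n)
      suit <- value_grid(sp, matrix(s, 1, n))
      p10 <- binarize_sdm(suit, 1:n, "p10")$threshold
      mtp <- binarize_sdm(suit, 1:n, "mtp")$threshold
      expect_equal(p10, sort(s)[ceiling(0.1 * n)])
      expect_equal(mtp, min(s))
      expect_gte(p10, mtp) # monotonicity of the rule
    }
  })
})

test_that("feature intersection counts candidates, drops empties, and conserves area", {
  sp <- toy_spec(3, 3)
  # partition into 3 PGDs by column
  pgd <- as_pgd_map(label_grid(sp, matrix(rep(1:3, each = 3), 3, 3)))
  full <- value_grid(sp, matrix(1, 3, 3))
  m <- matrix(1, 3, 3); m[, 3] <- 0 # taxon b misses zone 3
  sdm <- list(a = full, b = value_grid(sp, m))
  res <- intersect_features(sdm, pgd)
  expect_equal(res$candidate_count, 6)
  expect_equal(res$kept_count, 5)
  # per-taxon union of kept layers equals SDM on the land mask
  meta <- features_meta(res$features)
  for (tx in c("a", "b")) {
    cells <- sort(unlist(lapply(
      res$features$features[meta$taxon == tx], `[[`, "cells")))
    expect_equal(cells, which(as.vector(sdm[[tx]]$values) > 0))
  }
  expect_error(intersect_features(setNames(sdm, c("a", "a")), pgd),
               class = "pgdplan_error_features")
})

test_that("one SDM covering exactly one PGD yields one identical kept layer", {
  sp <- toy_spec(2, 2)
  pgd <- as_pgd_map(label_grid(sp, matrix(c(1L, 1L, 2L, 2L), 2, 2)))
  sdm <- list(x = value_grid(sp, matrix(c(1, 1, 0, 0), 2, 2)))
  res <- intersect_features(sdm, pgd)
  expect_equal(res$kept_count, 1)
  expect_equal(res$features$features[[1]]$cells, c(1L, 2L))
})

test_that("intensity split relabels by yield with an inclusive 3 t/ha boundary", {
  sp <- toy_spec(2, 3)
  lc <- label_grid(sp, matrix(c(3L, 1L, 3L, 3L, 2L, 3L), 2, 3))
  au <- label_grid(sp, matrix(c(1L, 1L, 1L, 2L, 2L, 3L), 2, 3))
  yields <- tibble::tibble(unit = 1:3, yield_t_ha = c(3.0, 3.2, 2.5))
  out <- intensity_split(lc, au, yields)
  # unit 1 at exactly 3.0 -> less intensive (boundary inclusive)
  expect_equal(out$labels[1, 1], 3L)
  # unit 2 above threshold -> intensive
  expect_equal(out$labels[2, 2], 4L)
  # unit 3 below -> less intensive
  expect_equal(out$labels[2, 3], 3L)
  # non-agricultural classes untouched
  expect_equal(out$labels[2, 1], 1L)

  # no agriculture: identity
  lc2 <- label_grid(sp, matrix(c(1L, 2L, 5L, 6L, 7L, 1L), 2, 3))
  expect_identical(intensity_split(lc2, au, yields)$labels, lc2$labels)

  # agriculture in a unit without a yield entry is an error naming the unit
  expect_error(intensity_split(lc, au, yields[1:2, ]), "3",
               class = "pgdplan_error_features")
})

test_that("habitat condition layers are class-wise lookups over {1, 0.5, 0.1}", {
  sp <- toy_spec(2, 3)
  lc <- label_grid(sp, matrix(c(1L, 5L, 2L, 0L, 7L, 3L), 2, 3))
  prefs <- c(1, 0.5, 1, 0.1, 0.1, 0.5, 0.1)
  cond <- habitat_condition(lc, prefs)
  expect_equal(as.vector(cond$values),
               c(1, 0.1, 0.5, NA, 0.1, 1)) # per-cell lookup oracle
  expect_true(all(cond$values %in% c(0.1, 0.5, 1) | is.na(cond$values)))

  expect_equal(unique(as.vector(
    habitat_condition(lc, rep(1, 7))$values[!is.na(cond$values)])), 1)
  expect_error(habitat_condition(label_grid(sp, matrix(8L, 2, 3)), prefs),
               class = "pgdplan_error_features")
  expect_error(habitat_condition(lc, rep(0.7, 7)),
               class = "pgdplan_error_features")
})

test_that("IUCN weights follow the category map, SSI taxa get 1, and 0 is preserved", {
  taxa <- tibble::tibble(
    taxon = c("t1", "t2", "t3", "t4", "t5"),
    iucn = c("EN", "VU", "NE", "LC", "CR"),
    weight = c(NA, NA, NA, 0, NA)
  )
  out <- assign_weights(taxa, ssi_ids = "t3")
  expect_equal(out$weight, c(1, 0.8, 1, 0, 1))
  expect_equal(unname(iucn_weights()[c("NT", "DD", "NE")]), c(0.5, 0.3, 0.1))
  expect_error(assign_weights(tibble::tibble(taxon = "x", iucn = "XX")),
               class = "pgdplan_error_taxa")
})

test_that("the taxon-metadata reader validates categories and sums counts", {
  counts_path <- system.file("extdata", "cwr_iucn_counts.csv", package = "pgdplan")
  counts <- read_iucn_counts(counts_path)
  taxa <- expand_iucn_counts(counts)
  expect_equal(nrow(taxa), sum(counts$n_taxa))
  expect_equal(sort(unique(taxa$iucn)), sort(counts$iucn))
  w <- assign_weights(taxa)
  expect_true(all(w$weight %in% iucn_weights()))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("iucn,n_taxa", "EW,3"), bad)
  expect_error(read_iucn_counts(bad), class = "pgdplan_error_taxa")
})

test_that("scenario builder assembles the five feature configurations", {
  world <- make_world(seed = 13, n_rows = 20, n_cols = 20, n_taxa = 5)
  sdm <- binarize_world(world)[sprintf("taxon_%02d", 1:5)]
  pgd <- world$pgd
  n_pgd <- nrow(pgd$provenance)
  n_lz <- nrow(world$lz$legend)

  expect_equal(length(build_scenario("SDM", sdm)$features), 5)
  expect_equal(length(build_scenario("SDM+LZ", sdm, lifezones = world$lz)$features),
               5 + n_lz)
  expect_equal(length(build_scenario("SDM+PGD", sdm, pgd = pgd)$features),
               5 + n_pgd)
  sxp <- build_scenario("SDMxPGD", sdm, pgd = pgd)
  expect_equal(length(sxp$features),
               intersect_features(sdm, pgd)$kept_count)
  admu <- build_scenario("ADMU", sdm, pgd = pgd)
  expect_equal(length(admu$features), 5)
  expect_s3_class(attr(admu, "units"), "pgd_map")
  expect_error(build_scenario("SDMxPGD", sdm), class = "pgdplan_error_features")

  # SSI point features are appended and never condition-linked
  ssi <- world$taxa$presences["ssi_01"]
  withssi <- build_scenario("SDM", sdm, ssi_points = ssi, conditions = TRUE)
  meta <- features_meta(withssi)
  expect_equal(sum(meta$kind == "points"), 1)
  expect_true(is.na(meta$condition[meta$kind == "points"]))
  expect_equal(meta$weight[meta$kind == "points"], 1)
})

test_that("crossing full-coverage layers with a 102-zone partition yields 11832 candidates", {
  # combinatorics check at desk scale: 116 all-covering distributions
  # against a 102-unit partition
  sp <- grid_spec(6, 17, cell_size = 1000) # 102 cells, one PGD each
  pgd <- as_pgd_map(label_grid(sp, matrix(1:102, 6, 17)))
  full <- value_grid(sp, matrix(1, 6, 17))
  sdm <- setNames(rep(list(full), 116), sprintf("t%03d", 1:116))
  res <- intersect_features(sdm, pgd)
  expect_equal(res$candidate_count, 11832)
  expect_equal(res$kept_count, 11832) # full coverage: nothing is empty
})
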