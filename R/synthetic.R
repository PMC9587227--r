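#' Synthetic-study configuration
#'
#' Parameters of the seeded synthetic landscapes used to exercise the whole
#' pipeline: grid shape and cell size (default 60 x 60 cells of 1 km, the
#' analysis resolution the method targets), climate gradients and noise,
#' divider cartography, taxa, and genetic-sample structure. Identical
#' configurations reproduce identical outputs bit-for-bit.
#'
#' @param seed Integer master seed; every stochastic operation derives its
#'   stream from it.
#' @param n_rows,n_cols Grid shape.
#' @param cell_size Cell side in map units (default 1000 m).
#' @param temp_south,temp_north Annual-mean temperature at the southern /
#'   northern grid edge, deg C (north-south gradient).
#' @param seasonal_amplitude Half-range of the monthly temperature cycle,
#'   deg C.
#' @param precip_west,precip_east Annual precipitation at the western /
#'   eastern edge, mm/yr (west-east gradient).
#' @param noise_sd_temp,noise_sd_precip Standard deviation of the spatially
#'   correlated noise added to temperature (deg C) and precipitation (mm).
#' @param noise_scale Gaussian smoothing scale of the noise, in cells.
#' @param divider_classes Integer vector: one divider raster per entry, with
#'   that many Voronoi classes.
#' @param n_admin_units Number of administrative units (Voronoi).
#' @param yield_mean,yield_sd Administrative-unit maize-yield distribution
#'   (t/ha), straddling the 3 t/ha intensity boundary.
#' @param n_taxa Number of modeled taxa (with suitability surfaces).
#' @param n_ssi Number of occurrence-only (SSI) taxa.
#' @param pgds_per_taxon Upper bound on the number of PGDs a taxon's range
#'   is seeded in (1..this, drawn per taxon).
#' @param kernel_bandwidth Suitability kernel bandwidth, in cells.
#' @param suitability_noise Multiplicative noise sd on suitability.
#' @param n_presences Presence records per modeled taxon (>= 20, the minimum
#'   the modeling step requires).
#' @param n_ssi_occurrences Occurrence records per SSI taxon.
#' @param n_samples Genetic sampling localities.
#' @param alpha Dirichlet concentration on the home cluster; large values
#'   give near-pure memberships, `alpha = 1` a flat (structure-free) draw.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_rows = 60L, n_cols = 60L,
                       cell_size = 1000, temp_south = 26, temp_north = 6,
                       seasonal_amplitude = 6, precip_west = 250,
                       precip_east = 2200, noise_sd_temp = 1.5,
                       noise_sd_precip = 150, noise_scale = 5,
                       divider_classes = c(3L, 4L), n_admin_units = 25L,
                       yield_mean = 3, yield_sd = 1, n_taxa = 8L,
                       n_ssi = 2L, pgds_per_taxon = 3L,
                       kernel_bandwidth = 8, suitability_noise = 0.1,
                       n_presences = 30L, n_ssi_occurrences = 5L,
                       n_samples = 200L, alpha = 50) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_rows >= 1, cfg$n_cols >= 1, cfg$alpha > 0,
            cfg$n_taxa >= 1, cfg$n_presences >= 1)
  structure(cfg, class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}

# spatially correlated noise: white noise smoothed by a separable Gaussian
# kernel (scale in cells), rescaled to unit sd
smooth_noise <- function(nr, nc, scale) {
  x <- matrix(rnorm(nr * nc), nr, nc)
  if (scale > 0) {
    smooth_1d <- function(n) {
      d <- abs(outer(seq_len(n), seq_len(n), `-`))
      k <- exp(-0.5 * (d / scale)^2)
      k / rowSums(k)
    }
    x <- smooth_1d(nr) %*% x %*% t(smooth_1d(nc))
  }
  x / stats::sd(x)
}

voronoi_labels <- function(spec, k) {
  nr <- spec$n_rows
  nc <- spec$n_cols
  sr <- runif(k, 0.5, nr + 0.5)
  sc <- runif(k, 0.5, nc + 0.5)
  r <- rep(seq_len(nr), times = nc)
  c <- rep(seq_len(nc), each = nr)
  d <- outer(r, sr, `-`)^2 + outer(c, sc, `-`)^2
  label_grid(spec, matrix(max.col(-d, ties.method = "first"), nr, nc))
}

#' Simulate a synthetic landscape
#'
#' Generates the raster and table inputs the pipeline consumes: a climate
#' stack (smooth north-south temperature and west-east precipitation
#' gradients plus seeded spatially correlated noise), Voronoi divider
#' cartography, a seven-category land-cover mosaic (intensive agriculture,
#' code 4, appears only after [intensity_split()]), Voronoi administrative
#' units, and per-unit yields drawn around the 3 t/ha intensity boundary.
#'
#' @param config A [sim_config()].
#' @return A list with `climate` ([climate_stack()]), `dividers` (named list
#'   of [label_grid()]s), `landcover`, `admin_units` ([label_grid()]s), and
#'   `yields` (tibble `unit`, `yield_t_ha`).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    sp <- grid_spec(config$n_rows, config$n_cols, origin_x = 0,
                    origin_y = config$n_rows * config$cell_size,
                    cell_size = config$cell_size, crs_id = "synthetic-metric")
    nr <- sp$n_rows
    nc <- sp$n_cols
    lat <- matrix(rep(seq(config$temp_north, config$temp_south, length.out = nr),
                      times = nc), nr, nc)
    tnoise <- smooth_noise(nr, nc, config$noise_scale) * config$noise_sd_temp
    monthly <- purrr::map(1:12, function(m) {
      season <- config$seasonal_amplitude * cos(2 * pi * (m - 7) / 12)
      value_grid(sp, lat + season + tnoise)
    })
    lon <- matrix(rep(seq(config$precip_west, config$precip_east, length.out = nc),
                      each = nr), nr, nc)
    pnoise <- smooth_noise(nr, nc, config$noise_scale) * config$noise_sd_precip
    precip <- value_grid(sp, pmax(lon + pnoise, 1))
    climate <- climate_stack(monthly, precip)
    dividers <- purrr::imap(
      setNames(as.list(config$divider_classes),
               paste0("divider", seq_along(config$divider_classes))),
      function(k, nm) voronoi_labels(sp, k)
    )
    landcover_seed <- voronoi_labels(sp, 60)
    lc_classes <- sample(c(1L, 2L, 3L, 5L, 6L, 7L), 60, replace = TRUE,
                         prob = c(0.35, 0.25, 0.2, 0.08, 0.07, 0.05))
    landcover <- label_grid(sp, matrix(lc_classes[landcover_seed$labels], nr, nc))
    admin_units <- voronoi_labels(sp, config$n_admin_units)
    yields <- tibble::tibble(
      unit = seq_len(config$n_admin_units),
      yield_t_ha = pmax(rnorm(config$n_admin_units, config$yield_mean,
                              config$yield_sd), 0.3)
    )
    list(climate = climate, dividers = dividers, landcover = landcover,
         admin_units = admin_units, yields = yields)
  })
}

#' Cycled divider assignment
#'
#' A simple deterministic stand-in for the expert choice of best-fitting
#' cartography: life zones are assigned one divider each, cycling through
#' the available divider names in zone-id order.
#'
#' @param lifezones A `life_zone_map`.
#' @param divider_names Character vector of divider names.
#' @return An assignment tibble (`zone_id`, `divider`).
#' @export
cycled_assignment <- function(lifezones, divider_names) {
  ids <- lifezones$legend$zone_id
  tibble::tibble(
    zone_id = ids,
    divider = divider_names[(ids - 1L) %% length(divider_names) + 1L]
  )
}

cell_centres <- function(cells, spec) {
  r <- (cells - 1L) %% spec$n_rows + 1L
  c <- (cells - 1L) %/% spec$n_rows + 1L
  tibble::tibble(x = spec$origin_x + (c - 0.5) * spec$cell_size,
                 y = spec$origin_y - (r - 0.5) * spec$cell_size)
}

#' Simulate taxa: suitability surfaces, presences, and metadata
#'
#' Each modeled taxon's suitability is a seeded Gaussian-kernel mixture
#' centred at random cells of a random subset of PGDs and restricted to
#' those PGDs (so ranges are nested in the proxy partition), with
#' multiplicative noise; presences are sampled proportional to suitability.
#' A configurable number of occurrence-only (SSI) taxa get no surface and
#' few occurrences. IUCN categories are drawn from a fixed categorical
#' distribution reflecting the skew of real assessments (mostly LC, few CR).
#'
#' @param config A [sim_config()].
#' @param pgd A `pgd_map`.
#' @return A list with `suitability` (named list of [value_grid()]s),
#'   `presences` (named list of tibbles `x`, `y`), and `taxa` (tibble
#'   `taxon`, `iucn`, `has_sdm`, `pref_1`..`pref_7`).
#' @export
simulate_taxa <- function(config, pgd) {
  stopifnot(inherits(config, "sim_config"), inherits(pgd, "pgd_map"))
  with_seed(config$seed + 1L, {
    sp <- pgd$zones$spec
    zl <- as.vector(pgd$zones$labels)
    pgd_ids <- pgd$provenance$pgd_id
    nr <- sp$n_rows
    rowv <- (seq_len(n_cells(sp)) - 1L) %% nr + 1L
    colv <- (seq_len(n_cells(sp)) - 1L) %/% nr + 1L
    taxa_ids <- sprintf("taxon_%02d", seq_len(config$n_taxa))
    ssi_ids <- sprintf("ssi_%02d", seq_len(config$n_ssi))
    suitability <- list()
    presences <- list()
    for (tx in taxa_ids) {
      n_home <- sample(seq_len(min(config$pgds_per_taxon, length(pgd_ids))), 1)
      home <- pgd_ids[sample.int(length(pgd_ids), n_home)]
      support <- which(zl %in% home)
      centres <- support[sample.int(length(support), n_home,
                                     replace = length(support) < n_home)]
      s <- numeric(n_cells(sp))
      for (cc in centres) {
        d2 <- (rowv - rowv[cc])^2 + (colv - colv[cc])^2
        s <- s + exp(-0.5 * d2 / config$kernel_bandwidth^2)
      }
      s <- s * exp(rnorm(length(s), 0, config$suitability_noise))
      out <- rep(NA_real_, n_cells(sp))
      out[zl > 0L] <- 0
      out[support] <- s[support] / max(s[support])
      suitability[[tx]] <- value_grid(sp, matrix(out, nr))
      prob <- s[support]
      cells <- support[sample.int(length(support), config$n_presences,
                                  replace = TRUE, prob = prob)]
      presences[[tx]] <- cell_centres(cells, sp)
    }
    land <- which(zl > 0L)
    for (tx in ssi_ids) {
      cells <- land[sample.int(length(land), config$n_ssi_occurrences,
                               replace = TRUE)]
      presences[[tx]] <- cell_centres(cells, sp)
    }
    all_ids <- c(taxa_ids, ssi_ids)
    cats <- sample(names(iucn_weights()), length(all_ids), replace = TRUE,
                   prob = c(0.03, 0.2, 0.07, 0.04, 0.09, 0.47, 0.1))
    prefs <- matrix(sample(c(1, 0.5, 0.1), length(all_ids) * 7, replace = TRUE,
                           prob = c(0.45, 0.3, 0.25)),
                    nrow = length(all_ids), ncol = 7,
                    dimnames = list(NULL, paste0("pref_", 1:7)))
    taxa <- dplyr::bind_cols(
      tibble::tibble(taxon = all_ids, iucn = cats,
                     has_sdm = all_ids %in% taxa_ids),
      tibble::as_tibble(prefs)
    )
    list(suitability = suitability, presences = presences, taxa = taxa)
  })
}

#' Simulate genetic samples with cluster-per-PGD structure
#'
#' Places sampling localities at random positive cells of a binary
#' distribution and draws each sample's admixture membership vector from a
#' Dirichlet distribution concentrated on its home PGD's cluster:
#' `alpha -> Inf` gives pure memberships (clusters identical to PGDs),
#' `alpha = 1` a flat draw with no geographic structure.
#'
#' @param config A [sim_config()] (`n_samples`, `alpha`).
#' @param pgd A `pgd_map`.
#' @param sdm Binary [value_grid()]; samples are placed on its positive
#'   cells (must be non-empty).
#' @param clusters_per_pgd Optional named integer vector mapping every PGD
#'   id overlapping the distribution to a cluster index; default maps each
#'   such PGD to its own cluster.
#' @return A tibble with `sample_id`, `x`, `y`, `true_cluster`, and
#'   membership columns `cluster_1`..`cluster_K` (rows sum to 1).
#' @export
simulate_genetics <- function(config, pgd, sdm, clusters_per_pgd = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(pgd, "pgd_map"))
  check_alignment(pgd$zones, sdm)
  pos <- grid_positive_cells(sdm)
  pos <- pos[as.vector(pgd$zones$labels)[pos] > 0L]
  if (length(pos) == 0) {
    rlang::abort("distribution is empty (no positive land cells)",
                 class = "pgdplan_error_synthetic")
  }
  overlapping <- sort(unique(as.vector(pgd$zones$labels)[pos]))
  if (is.null(clusters_per_pgd)) {
    clusters_per_pgd <- setNames(seq_along(overlapping), overlapping)
  }
  if (!all(as.character(overlapping) %in% names(clusters_per_pgd))) {
    rlang::abort("clusters_per_pgd must map every PGD overlapping the distribution",
                 class = "pgdplan_error_synthetic")
  }
  K <- max(clusters_per_pgd)
  with_seed(config$seed + 2L, {
    cells <- pos[sample.int(length(pos), config$n_samples, replace = TRUE)]
    home_pgd <- as.vector(pgd$zones$labels)[cells]
    home_cluster <- unname(clusters_per_pgd[as.character(home_pgd)])
    memb <- matrix(vapply(home_cluster, function(k) {
      a <- rep(1, K)
      a[k] <- config$alpha
      g <- rgamma(K, shape = a, rate = 1)
      g / sum(g)
    }, numeric(K)), nrow = length(home_cluster), ncol = K, byrow = TRUE)
    colnames(memb) <- paste0("cluster_", seq_len(K))
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("s%04d", seq_len(config$n_samples))),
      cell_centres(cells, pgd$zones$spec),
      tibble::tibble(true_cluster = home_cluster),
      tibble::as_tibble(memb)
    )
  })
}
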