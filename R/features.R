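#' Land-cover categories
#'
#' The seven aggregated land-cover categories used for habitat preference:
#' 1 primary vegetation, 2 secondary vegetation, 3 less intensive rainfed
#' and moisture agriculture, 4 intensive rainfed and moisture agriculture,
#' 5 irrigated agriculture, 6 induced and cultivated grasslands and forests,
#' 7 urban. Before [intensity_split()] a land-cover map carries all rainfed
#' and moisture agriculture under code 3.
#'
#' @return A tibble with columns `code` and `name`.
#' @export
landcover_classes <- function() {
  tibble::tibble(
    code = 1:7,
    name = c(
      "primary vegetation", "secondary vegetation",
      "less intensive rainfed/moisture agriculture",
      "intensive rainfed/moisture agriculture",
      "irrigated agriculture",
      "induced/cultivated grasslands and forests", "urban"
    )
  )
}

#' IUCN threat-category weights
#'
#' The weights given to taxa by extinction-risk category when ranking the
#' landscape: CR 1, EN 1, VU 0.8, NT 0.5, DD 0.3, LC 0.2, NE 0.1.
#'
#' @return A named numeric vector keyed by category code.
#' @export
iucn_weights <- function() {
  c(CR = 1, EN = 1, VU = 0.8, NT = 0.5, DD = 0.3, LC = 0.2, NE = 0.1)
}

#' Read taxon metadata
#'
#' `read_taxon_table()` reads a per-taxon metadata CSV (columns `taxon`,
#' `iucn`, optionally `weight`, `has_sdm`, habitat-preference columns
#' `pref_1`..`pref_7`). `read_iucn_counts()` reads a per-category summary
#' table (columns `iucn`, `n_taxa`), as published risk assessments print
#' them, and `expand_iucn_counts()` turns such a summary into one metadata
#' row per taxon. Unknown category codes are an error.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_taxon_table <- function(path) {
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("taxon", "iucn") %in% names(tab))) {
    rlang::abort("taxon table needs columns 'taxon' and 'iucn'",
                 class = "pgdplan_error_taxa")
  }
  check_iucn(tab$iucn)
  tab
}

#' @rdname read_taxon_table
#' @export
read_iucn_counts <- function(path) {
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("iucn", "n_taxa") %in% names(tab))) {
    rlang::abort("counts table needs columns 'iucn' and 'n_taxa'",
                 class = "pgdplan_error_taxa")
  }
  check_iucn(tab$iucn)
  tab
}

#' @param counts A tibble as returned by `read_iucn_counts()`.
#' @rdname read_taxon_table
#' @export
expand_iucn_counts <- function(counts) {
  counts |>
    dplyr::rowwise() |>
    dplyr::reframe(taxon = sprintf("%s_%03d", .data$iucn, seq_len(.data$n_taxa)),
                   iucn = .data$iucn)
}

check_iucn <- function(x) {
  bad <- setdiff(unique(x), names(iucn_weights()))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown IUCN category: ", paste(bad, collapse = ", ")),
                 class = "pgdplan_error_taxa")
  }
  invisible(x)
}

#' Assign ranking weights to taxa
#'
#' Fills the `weight` column of a taxon table from the IUCN category map
#' (see [iucn_weights()]). Taxa listed in `ssi_ids` (species of special
#' interest, represented only by occurrence points) are all weighted 1. An
#' explicit pre-existing weight (including 0, which excludes a feature from
#' ranking while keeping it for evaluation) is never overridden.
#'
#' @param taxa Tibble with columns `taxon`, `iucn`, optionally `weight`.
#' @param ssi_ids Character vector of SSI taxon ids.
#' @return The taxon table with a filled `weight` column.
#' @export
assign_weights <- function(taxa, ssi_ids = character(0)) {
  taxa <- tibble::as_tibble(taxa)
  check_iucn(taxa$iucn)
  w <- iucn_weights()[taxa$iucn]
  w[taxa$taxon %in% ssi_ids] <- 1
  if ("weight" %in% names(taxa)) {
    w <- ifelse(is.na(taxa$weight), w, taxa$weight)
  }
  dplyr::mutate(taxa, weight = unname(w))
}

#' Binarize a suitability raster at a presence-based threshold
#'
#' Converts a continuous species-distribution-model suitability surface into
#' a presence/absence map. The threshold is an order statistic of the
#' suitability values at the training presences: `"p10"` uses the k-th
#' smallest presence suitability with `k = ceiling(0.1 * n)` (the ten-
#' percentile training threshold), `"mtp"` the smallest (minimum training
#' presence). Cells with suitability at or above the threshold become 1.
#'
#' @param suitability A [value_grid()] of continuous suitabilities.
#' @param presence_cells Integer linear cell indices of the presences, or a
#'   tibble from [points_to_cells()] (its `cell` column is used; outside
#'   points are ignored).
#' @param rule `"p10"` or `"mtp"`.
#' @return A list with `grid` (binary [value_grid()], nodata propagated) and
#'   `threshold`.
#' @export
binarize_sdm <- function(suitability, presence_cells, rule = c("p10", "mtp")) {
  rule <- match.arg(rule)
  stopifnot(inherits(suitability, "value_grid"))
  if (is.data.frame(presence_cells)) {
    presence_cells <- presence_cells$cell[!presence_cells$outside]
  }
  s <- as.vector(suitability$values)[presence_cells]
  s <- s[!is.na(s)]
  if (length(s) == 0) {
    rlang::abort("no presence falls on a non-nodata suitability cell",
                 class = "pgdplan_error_features")
  }
  thr <- if (rule == "mtp") min(s) else sort(s)[ceiling(0.1 * length(s))]
  v <- suitability$values
  bin <- ifelse(is.na(v), NA_real_, as.numeric(v >= thr))
  list(grid = value_grid(suitability$spec, bin), threshold = thr)
}

new_feature_layer <- function(feature_id, taxon, pgd_id, kind, cells, values,
                              weight = 1, condition = NA_character_) {
  if (any(values < 0)) {
    rlang::abort("feature values must be >= 0", class = "pgdplan_error_features")
  }
  list(feature_id = feature_id, taxon = taxon, pgd_id = as.integer(pgd_id),
       kind = kind, cells = as.integer(cells), values = as.numeric(values),
       weight = weight, condition = condition)
}

new_feature_set <- function(features, spec, scenario = "custom") {
  ids <- purrr::map_chr(features, "feature_id")
  if (anyDuplicated(ids)) {
    rlang::abort("feature ids must be unique", class = "pgdplan_error_features")
  }
  structure(list(features = features, spec = spec, scenario = scenario),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> scenario '%s', %d features on %s\n",
              x$scenario, length(x$features), format(x$spec)))
  invisible(x)
}

#' Feature metadata table
#'
#' @param features A `feature_set`.
#' @return Tibble with one row per feature: `feature_id`, `taxon`, `pgd_id`,
#'   `kind`, `weight`, `condition`, `n_cells`, `total_value`.
#' @export
features_meta <- function(features) {
  stopifnot(inherits(features, "feature_set"))
  purrr::map_dfr(features$features, function(f) {
    tibble::tibble(
      feature_id = f$feature_id, taxon = f$taxon, pgd_id = f$pgd_id,
      kind = f$kind, weight = f$weight, condition = f$condition,
      n_cells = length(f$cells), total_value = sum(f$values)
    )
  })
}

#' @export
tidy.feature_set <- function(x, ...) features_meta(x)

#' @export
glance.feature_set <- function(x, ...) {
  m <- features_meta(x)
  tibble::tibble(
    scenario = x$scenario, n_features = nrow(m),
    n_taxa = dplyr::n_distinct(m$taxon[!is.na(m$taxon)]),
    n_point_features = sum(m$kind == "points")
  )
}

grid_positive_cells <- function(grid) {
  v <- as.vector(grid$values)
  which(!is.na(v) & v > 0)
}

#' Intersect species distributions with PGD zones
#'
#' Crosses every binarized species distribution with every proxy of genetic
#' differentiation: the candidate count is `n_taxa * n_pgd`; each non-empty
#' (taxon, PGD) overlap becomes one conservation feature restricted to the
#' cells where both are positive, and empty intersections are dropped. Per
#' taxon, the union of the kept layers equals the distribution intersected
#' with the land mask.
#'
#' @param sdm_layers Named list of binary [value_grid()]s (names are taxon
#'   ids; duplicate names are an error).
#' @param pgd A `pgd_map`.
#' @param weights Optional named numeric vector of per-taxon weights
#'   (default 1).
#' @param conditions Logical; if `TRUE`, layers carry a condition link to
#'   their taxon's habitat layer.
#' @return A list with `features` (a `feature_set`), `candidate_count`, and
#'   `kept_count`.
#' @export
intersect_features <- function(sdm_layers, pgd, weights = NULL,
                               conditions = FALSE) {
  stopifnot(inherits(pgd, "pgd_map"))
  taxa <- names(sdm_layers)
  if (is.null(taxa) || anyDuplicated(taxa)) {
    rlang::abort("sdm_layers must be uniquely named by taxon",
                 class = "pgdplan_error_features")
  }
  check_alignment(c(unname(sdm_layers), list(pgd$zones)))
  zl <- as.vector(pgd$zones$labels)
  pgd_ids <- pgd$provenance$pgd_id
  candidate_count <- length(taxa) * length(pgd_ids)
  features <- list()
  for (tx in taxa) {
    pos <- grid_positive_cells(sdm_layers[[tx]])
    labs <- zl[pos]
    keep <- labs > 0L
    split_cells <- split(pos[keep], labs[keep])
    for (zid in names(split_cells)) {
      cells <- split_cells[[zid]]
      features[[length(features) + 1]] <- new_feature_layer(
        feature_id = paste0(tx, "@pgd", zid), taxon = tx,
        pgd_id = as.integer(zid), kind = "raster",
        cells = cells, values = rep(1, length(cells)),
        weight = if (is.null(weights)) 1 else unname(weights[tx]),
        condition = if (conditions) tx else NA_character_
      )
    }
  }
  list(
    features = new_feature_set(features, pgd$zones$spec, scenario = "SDMxPGD"),
    candidate_count = candidate_count,
    kept_count = length(features)
  )
}

#' Split agriculture by cultivation intensity
#'
#' Relabels rainfed/moisture-agriculture cells (land-cover code 3) as less
#' intensive (code 3) where the administrative unit's average yield is less
#' than or equal to the threshold (default 3 t/ha, boundary inclusive), and
#' as intensive (code 4) otherwise. All other classes pass through.
#'
#' @param landcover A [label_grid()] using the [landcover_classes()] codes.
#' @param admin_units A [label_grid()] of administrative-unit ids.
#' @param yields Tibble with columns `unit` and `yield_t_ha`.
#' @param threshold Yield threshold in t/ha; default 3.
#' @return A [label_grid()] with agriculture split into codes 3 and 4.
#' @export
intensity_split <- function(landcover, admin_units, yields, threshold = 3) {
  check_alignment(landcover, admin_units)
  lc <- as.vector(landcover$labels)
  au <- as.vector(admin_units$labels)
  ag <- which(lc == 3L)
  if (length(ag) > 0) {
    units_needed <- sort(unique(au[ag]))
    missing <- setdiff(units_needed, yields$unit)
    if (length(missing) > 0) {
      rlang::abort(paste0("no yield for administrative units with agriculture: ",
                          paste(missing, collapse = ", ")),
                   class = "pgdplan_error_features")
    }
    y <- yields$yield_t_ha[match(au[ag], yields$unit)]
    lc[ag] <- ifelse(y <= threshold, 3L, 4L)
  }
  label_grid(landcover$spec, matrix(lc, landcover$spec$n_rows))
}

#' Taxon habitat-condition layer
#'
#' Maps each land-cover cell to the taxon's expert habitat-preference score
#' (1 high preference, 0.5 low preference, 0.1 no preference) over the seven
#' aggregated categories, producing the per-taxon condition raster that
#' down-weights feature value in unsuitable land cover.
#'
#' @param landcover A [label_grid()] using [landcover_classes()] codes 1..7
#'   (0 = nodata).
#' @param prefs Numeric vector of length 7 (preference per category code),
#'   values in `{1, 0.5, 0.1}`.
#' @return A [value_grid()] of preference scores; nodata propagated.
#' @export
habitat_condition <- function(landcover, prefs) {
  stopifnot(inherits(landcover, "label_grid"))
  if (length(prefs) != 7 || !all(prefs %in% c(1, 0.5, 0.1))) {
    rlang::abort("prefs must give a score in {1, 0.5, 0.1} for each of the 7 categories",
                 class = "pgdplan_error_features")
  }
  lc <- as.vector(landcover$labels)
  bad <- setdiff(unique(lc), 0:7)
  if (length(bad) > 0) {
    rlang::abort(paste0("land-cover classes outside the seven categories: ",
                        paste(bad, collapse = ", ")),
                 class = "pgdplan_error_features")
  }
  idx <- ifelse(lc == 0L, NA_integer_, lc)
  v <- prefs[idx]
  value_grid(landcover$spec, matrix(v, landcover$spec$n_rows))
}

partition_features <- function(pgd, prefix = "pgd") {
  purrr::map(pgd$provenance$pgd_id, function(zid) {
    cells <- which(as.vector(pgd$zones$labels) == zid)
    new_feature_layer(
      feature_id = paste0(prefix, zid), taxon = NA_character_, pgd_id = zid,
      kind = "raster", cells = cells, values = rep(1, length(cells))
    )
  })
}

#' Build a scenario feature set
#'
#' Assembles the conservation-feature stack for one of the five scenario
#' configurations used to compare ways of carrying intraspecific
#' differentiation into the prioritization:
#' * `"SDM"` - one feature per taxon distribution;
#' * `"SDM+LZ"` - taxon features plus one binary feature per life zone;
#' * `"SDM+PGD"` - taxon features plus one binary feature per PGD;
#' * `"SDMxPGD"` - every non-empty taxon x PGD intersection as its own
#'   feature (see [intersect_features()]);
#' * `"ADMU"` - taxon features, with the PGD map attached as planning-unit
#'   strata for [admu_rank()].
#'
#' SSI occurrence tables, when supplied, are appended as point features
#' (value 1 per occurrence cell, weight 1, never condition-linked) in any
#' scenario. Weights default to uniform 1 for scenario comparison; pass a
#' named vector (e.g. from [assign_weights()]) for a weighted run.
#'
#' @param tag Scenario tag, one of the five above.
#' @param sdm_layers Named list of binary [value_grid()]s by taxon.
#' @param pgd A `pgd_map` (required for the PGD-dependent tags).
#' @param lifezones A `life_zone_map` (required for `"SDM+LZ"`).
#' @param ssi_points Optional named list (by taxon) of occurrence tibbles
#'   with `x`, `y` columns.
#' @param weights Optional named per-taxon weights.
#' @param conditions Logical; link taxon raster features to their habitat
#'   condition layers.
#' @return A `feature_set`; for `"ADMU"` the PGD map is attached as the
#'   `units` attribute.
#' @export
build_scenario <- function(tag = c("SDM", "SDM+LZ", "SDM+PGD", "SDMxPGD", "ADMU"),
                           sdm_layers, pgd = NULL, lifezones = NULL,
                           ssi_points = NULL, weights = NULL,
                           conditions = FALSE) {
  tag <- match.arg(tag)
  taxa <- names(sdm_layers)
  spec <- check_alignment(sdm_layers)
  if (tag %in% c("SDM+PGD", "SDMxPGD", "ADMU") && is.null(pgd)) {
    rlang::abort(paste0("scenario ", tag, " needs a PGD map"),
                 class = "pgdplan_error_features")
  }
  taxon_features <- purrr::imap(sdm_layers, function(g, tx) {
    cells <- grid_positive_cells(g)
    new_feature_layer(
      feature_id = tx, taxon = tx, pgd_id = 0L, kind = "raster",
      cells = cells, values = rep(1, length(cells)),
      weight = if (is.null(weights)) 1 else unname(weights[tx]),
      condition = if (conditions) tx else NA_character_
    )
  })
  features <- switch(tag,
    "SDM" = , "ADMU" = unname(taxon_features),
    "SDM+LZ" = c(unname(taxon_features),
                 partition_features(as_pgd_map(lifezones), prefix = "lz")),
    "SDM+PGD" = c(unname(taxon_features), partition_features(pgd)),
    "SDMxPGD" = intersect_features(sdm_layers, pgd, weights = weights,
                                   conditions = conditions)$features$features
  )
  if (!is.null(ssi_points)) {
    ssi_features <- purrr::imap(ssi_points, function(pts, tx) {
      mapped <- points_to_cells(pts, spec)
      cells <- unique(mapped$cell[!mapped$outside])
      new_feature_layer(
        feature_id = paste0("ssi:", tx), taxon = tx, pgd_id = 0L,
        kind = "points", cells = cells, values = rep(1, length(cells)),
        weight = 1
      )
    })
    features <- c(features, unname(ssi_features))
  }
  fs <- new_feature_set(features, spec, scenario = tag)
  if (tag == "ADMU") attr(fs, "units") <- pgd
  fs
}
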