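#' Climate stack
#'
#' Bundles the 13 aligned climate rasters the Holdridge classification needs:
#' twelve monthly mean temperatures (deg C) and one annual precipitation
#' total (mm/yr).
#'
#' @param monthly_temperature List of 12 [value_grid()]s of monthly mean
#'   temperature in deg C (January..December order is conventional but not
#'   required; only the set matters).
#' @param annual_precipitation A [value_grid()] of annual precipitation in
#'   mm/yr; must be non-negative outside nodata.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(monthly_temperature, annual_precipitation) {
  if (length(monthly_temperature) != 12) {
    rlang::abort(sprintf("need 12 monthly temperature grids, got %d",
                         length(monthly_temperature)),
                 class = "pgdplan_error_climate")
  }
  check_alignment(c(monthly_temperature, list(annual_precipitation)))
  p <- annual_precipitation$values
  if (any(p < 0, na.rm = TRUE)) {
    rlang::abort("annual precipitation must be >= 0 outside nodata",
                 class = "pgdplan_error_climate")
  }
  structure(list(monthly_temperature = monthly_temperature,
                 annual_precipitation = annual_precipitation),
            class = "climate_stack")
}

#' Holdridge biotemperature
#'
#' Mean annual biotemperature: the average of the twelve monthly mean
#' temperatures after clamping each month to the interval `[0, 30]` deg C
#' (months below freezing and above 30 deg C contribute 0 and 30
#' respectively, reflecting the range in which vegetative growth occurs).
#' Cells where any month is nodata are nodata.
#'
#' @param monthly_temperature List of 12 aligned [value_grid()]s, deg C.
#' @return A [value_grid()] of biotemperature in deg C (values in `[0, 30]`).
#' @export
biotemperature <- function(monthly_temperature) {
  if (length(monthly_temperature) != 12) {
    rlang::abort(sprintf("need 12 monthly temperature grids, got %d",
                         length(monthly_temperature)),
                 class = "pgdplan_error_climate")
  }
  spec <- check_alignment(monthly_temperature)
  acc <- matrix(0, spec$n_rows, spec$n_cols)
  for (g in monthly_temperature) {
    acc <- acc + pmin(pmax(g$values, 0), 30)
  }
  value_grid(spec, acc / 12)
}

#' Potential-evapotranspiration ratio
#'
#' The Holdridge PET ratio, `58.93 * biotemperature / precipitation`
#' (dimensionless): annual potential evapotranspiration in mm is 58.93 mm
#' per degree of biotemperature, and the ratio to annual precipitation
#' indexes the humidity province (> 1 means demand exceeds supply, i.e.
#' drier than humid).
#'
#' @param biotemp [value_grid()] of biotemperature, deg C.
#' @param precipitation [value_grid()] of annual precipitation, mm/yr;
#'   must be strictly positive on every non-nodata biotemperature cell.
#' @return A [value_grid()] of the dimensionless PET ratio.
#' @export
pet_ratio <- function(biotemp, precipitation) {
  check_alignment(biotemp, precipitation)
  bt <- biotemp$values
  p <- precipitation$values
  bad <- which(!is.na(bt) & !is.na(p) & p == 0)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("zero precipitation on non-nodata cells (linear indices): ",
             paste(head(bad, 20), collapse = ", ")),
      class = "pgdplan_error_climate"
    )
  }
  value_grid(biotemp$spec, PET_MM_PER_DEGREE * bt / p)
}

# Holdridge constants: annual PET mm per deg C of biotemperature, and the
# log2-spaced class boundaries of the latitudinal belts / humidity provinces
PET_MM_PER_DEGREE <- 58.93
BELT_BOUNDS <- c(1.5, 3, 6, 12, 24)
HUMIDITY_BOUNDS <- c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16, 32)

#' Belt / humidity interval indices
#'
#' `holdridge_belt()` maps biotemperature (deg C) to the latitudinal-belt
#' index 1..6 using half-open intervals lower-inclusive at each boundary
#' (1.5, 3, 6, 12, 24), so a biotemperature of exactly 12 falls in the
#' warm-temperate belt. `holdridge_humidity()` maps the PET ratio to the
#' humidity-province index 1..10 with half-open, upper-exclusive intervals
#' at 0.125, 0.25, 0.5, 1, 2, 4, 8, 16, 32.
#'
#' @param biotemp Numeric vector of biotemperatures, deg C.
#' @param ratio Numeric vector of PET ratios.
#' @return Integer vector of interval indices (`NA` propagated).
#' @export
holdridge_belt <- function(biotemp) {
  findInterval(biotemp, BELT_BOUNDS) + 1L
}

#' @rdname holdridge_belt
#' @export
holdridge_humidity <- function(ratio) {
  findInterval(ratio, HUMIDITY_BOUNDS) + 1L
}

holdridge_chart <- function() {
  path <- system.file("extdata", "holdridge_chart.csv", package = "pgdplan")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Classify a climate stack into Holdridge life zones
#'
#' Computes biotemperature and the PET ratio per cell, looks up the
#' latitudinal belt and humidity province on the Holdridge lattice, and
#' labels each occupied (belt, humidity) combination as one life zone.
#' Zone ids are consecutive integers from 1, ordered by (belt, humidity),
#' so identical climates always produce identical maps and legends. The
#' frost-line subdivision and transitional hexagon triangles of the full
#' Holdridge chart are not used; classification is on the basic
#' belt x humidity lattice.
#'
#' @param climate A [climate_stack()].
#' @return An object of class `life_zone_map`: a list with `zones` (a
#'   [label_grid()], 0 outside the climate mask) and `legend` (a tibble with
#'   columns `zone_id`, `belt`, `humidity`, `name`).
#' @export
classify_lifezones <- function(climate) {
  stopifnot(inherits(climate, "climate_stack"))
  bt <- biotemperature(climate$monthly_temperature)
  ratio <- pet_ratio(bt, climate$annual_precipitation)
  belt <- holdridge_belt(bt$values)
  hum <- holdridge_humidity(ratio$values)
  combo <- ifelse(is.na(belt) | is.na(hum), NA, (belt - 1L) * 100L + hum)
  occupied <- sort(unique(combo[!is.na(combo)]))
  zone_of <- match(combo, occupied)
  zones <- matrix(ifelse(is.na(zone_of), 0L, zone_of),
                  bt$spec$n_rows, bt$spec$n_cols)
  chart <- holdridge_chart()
  legend <- tibble::tibble(
    zone_id = seq_along(occupied),
    belt = occupied %/% 100L + 1L,
    humidity = occupied %% 100L
  ) |>
    dplyr::left_join(dplyr::select(chart, "belt", "humidity", "name"),
                     by = c("belt", "humidity"))
  structure(list(zones = label_grid(bt$spec, zones), legend = legend),
            class = "life_zone_map")
}

#' @export
print.life_zone_map <- function(x, ...) {
  cat(sprintf("<life_zone_map> %s, %d life zones\n",
              format(x$zones$spec), nrow(x$legend)))
  print(x$legend, n = 10)
  invisible(x)
}

#' @export
tidy.life_zone_map <- function(x, ...) {
  tidy(x$zones) |>
    dplyr::rename(zone_id = "value") |>
    dplyr::left_join(x$legend, by = "zone_id")
}

#' @export
glance.life_zone_map <- function(x, ...) {
  tibble::tibble(
    n_zones = nrow(x$legend),
    n_cells = sum(x$zones$labels > 0L),
    n_belts = dplyr::n_distinct(x$legend$belt),
    n_humidity = dplyr::n_distinct(x$legend$humidity)
  )
}
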