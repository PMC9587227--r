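#' Divider set
#'
#' Historical-isolation cartography used to subdivide life zones: one or more
#' categorical rasters (biogeographic provinces, watersheds, edaphology, ...)
#' plus an assignment table saying which dividers apply within each life
#' zone. The assignment mirrors the expert choice of the best-fitting
#' cartography per life zone: a zone absent from the table (or with no rows)
#' is left undivided.
#'
#' @param dividers Named list of [label_grid()]s, all aligned.
#' @param assignment Data frame with columns `zone_id` (integer life-zone id)
#'   and `divider` (name of a divider in `dividers`); one row per
#'   (zone, divider) pair, applied in row order within each zone.
#' @return An object of class `divider_set`.
#' @export
divider_set <- function(dividers, assignment) {
  stopifnot(is.list(dividers), length(dividers) >= 1)
  if (is.null(names(dividers)) || any(names(dividers) == "")) {
    rlang::abort("dividers must be a named list", class = "pgdplan_error_divider")
  }
  check_alignment(dividers)
  assignment <- tibble::as_tibble(assignment)
  if (nrow(assignment) > 0) {
    missing <- setdiff(unique(assignment$divider), names(dividers))
    if (length(missing) > 0) {
      rlang::abort(paste0("assignment names unknown dividers: ",
                          paste(missing, collapse = ", ")),
                   class = "pgdplan_error_divider")
    }
  }
  structure(list(dividers = dividers, assignment = assignment),
            class = "divider_set")
}

#' Subdivide life zones into proxies of genetic differentiation
#'
#' Within each life zone, cells are partitioned by the joint class of the
#' dividers assigned to that zone; every occupied (life zone x divider-class
#' combination) with at least one cell becomes one proxy of genetic
#' differentiation (PGD). PGD ids are consecutive integers from 1, ordered by
#' (life-zone id, divider class tuple), so identical inputs always produce
#' identical labelings. PGDs need not be spatially connected. A divider label
#' of 0 on a land cell is treated as its own "unclassified" class so that
#' coverage of the land mask is preserved.
#'
#' @param lifezones A `life_zone_map` (see [classify_lifezones()]), or any
#'   [label_grid()] partition to subdivide.
#' @param dividers A [divider_set()] aligned to the life-zone grid.
#' @return An object of class `pgd_map`: list with `zones` (a [label_grid()]
#'   of PGD ids, 0 outside the mask) and `provenance` (tibble with columns
#'   `pgd_id`, `zone_id`, `combo`, `n_cells`).
#' @export
subdivide_lifezones <- function(lifezones, dividers) {
  zgrid <- if (inherits(lifezones, "life_zone_map")) lifezones$zones else lifezones
  stopifnot(inherits(zgrid, "label_grid"), inherits(dividers, "divider_set"))
  check_alignment(c(list(zgrid), dividers$dividers))
  z <- as.vector(zgrid$labels)
  zone_ids <- sort(setdiff(unique(z), 0L))
  asg <- dividers$assignment
  pieces <- purrr::map(zone_ids, function(zid) {
    cells <- which(z == zid)
    div_names <- if (nrow(asg) > 0) asg$divider[asg$zone_id == zid] else character(0)
    if (length(div_names) == 0) {
      key <- matrix(0L, nrow = length(cells), ncol = 0)
      combo <- rep("", length(cells))
    } else {
      key <- vapply(div_names,
                    function(d) as.vector(dividers$dividers[[d]]$labels)[cells],
                    integer(length(cells)))
      key <- matrix(key, nrow = length(cells))
      combo <- apply(key, 1, function(r)
        paste(paste0(div_names, "=", r), collapse = "|"))
    }
    out <- tibble::tibble(cell = cells, zone_id = zid, combo = combo)
    if (ncol(key) > 0) {
      colnames(key) <- paste0("k", seq_len(ncol(key)))
      out <- dplyr::bind_cols(out, tibble::as_tibble(key))
    }
    out
  })
  all <- dplyr::bind_rows(pieces)
  key_cols <- grep("^k[0-9]+$", names(all), value = TRUE)
  groups <- all |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("zone_id", key_cols, "combo")))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c("zone_id", key_cols))))
  groups$pgd_id <- seq_len(nrow(groups))
  all <- dplyr::left_join(all, groups, by = c("zone_id", key_cols, "combo"))
  labels <- integer(n_cells(zgrid$spec))
  labels[all$cell] <- all$pgd_id
  provenance <- all |>
    dplyr::count(.data$pgd_id, .data$zone_id, .data$combo, name = "n_cells") |>
    dplyr::arrange(.data$pgd_id)
  new_pgd_map(label_grid(zgrid$spec, matrix(labels, zgrid$spec$n_rows)),
              provenance)
}

new_pgd_map <- function(zones, provenance, log = character(0)) {
  structure(list(zones = zones, provenance = provenance, log = log),
            class = "pgd_map")
}

#' Treat an existing partition as a PGD map
#'
#' Wraps any label partition (e.g. a life-zone map itself, or a single
#' landscape-wide unit) in the `pgd_map` container so it can be used as
#' planning units or intersection strata.
#'
#' @param zones A [label_grid()] whose positive labels partition the mask.
#' @return A `pgd_map` with trivial provenance (`zone_id` = label itself).
#' @export
as_pgd_map <- function(zones) {
  if (inherits(zones, "life_zone_map")) zones <- zones$zones
  stopifnot(inherits(zones, "label_grid"))
  ids <- sort(setdiff(unique(as.vector(zones$labels)), 0L))
  relab <- match(as.vector(zones$labels), ids)
  lab <- matrix(ifelse(is.na(relab), 0L, relab), zones$spec$n_rows)
  prov <- tibble::tibble(
    pgd_id = seq_along(ids), zone_id = ids, combo = "",
    n_cells = as.integer(tabulate(lab[lab > 0L], length(ids)))
  )
  new_pgd_map(label_grid(zones$spec, lab), prov)
}

# rook-adjacency neighbours of linear cell indices (column-major)
rook_neighbours <- function(cells, nr, nc) {
  r <- (cells - 1L) %% nr + 1L
  c <- (cells - 1L) %/% nr + 1L
  nb <- c(
    ifelse(r > 1L, cells - 1L, NA), ifelse(r < nr, cells + 1L, NA),
    ifelse(c > 1L, cells - nr, NA), ifelse(c < nc, cells + nr, NA)
  )
  nb[!is.na(nb)]
}

#' Merge or drop PGD fragments below a size threshold
#'
#' PGDs with fewer than `min_cells` cells are absorbed into the largest
#' rook-adjacent PGD of the same life zone; a fragment with no same-zone
#' neighbour is dropped to nodata and logged. Fragments are processed in
#' increasing size order (ties by id) against the evolving map, surviving
#' PGDs are relabeled consecutively, and the partition / nesting invariants
#' are preserved. `min_cells = 0` (the default elsewhere in the package)
#' returns the input unchanged.
#'
#' @param pgd A `pgd_map`.
#' @param min_cells Minimum PGD size in cells (>= 0).
#' @return A `pgd_map`; merges and drops are recorded in its `log`.
#' @export
filter_fragments <- function(pgd, min_cells) {
  stopifnot(inherits(pgd, "pgd_map"), min_cells >= 0)
  if (min_cells == 0) return(pgd)
  sp <- pgd$zones$spec
  lab <- as.vector(pgd$zones$labels)
  prov <- pgd$provenance
  zone_of <- setNames(prov$zone_id, prov$pgd_id)
  log <- pgd$log
  repeat {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab, 1L))
    present <- which(sizes > 0L)
    small <- present[sizes[present] < min_cells]
    if (length(small) == 0) break
    target <- small[order(sizes[small], small)][1]
    cells <- which(lab == target)
    nb <- rook_neighbours(cells, sp$n_rows, sp$n_cols)
    nb_lab <- setdiff(unique(lab[nb]), c(0L, target))
    same_zone <- nb_lab[zone_of[as.character(nb_lab)] == zone_of[as.character(target)]]
    if (length(same_zone) > 0) {
      absorber <- same_zone[order(-sizes[same_zone], same_zone)][1]
      lab[cells] <- absorber
      log <- c(log, sprintf("merged pgd %d (%d cells) into pgd %d",
                            target, length(cells), absorber))
    } else {
      lab[cells] <- 0L
      log <- c(log, sprintf("dropped pgd %d (%d cells) to nodata",
                            target, length(cells)))
    }
  }
  survivors <- sort(unique(lab[lab > 0L]))
  relab <- match(lab, survivors)
  lab <- ifelse(is.na(relab), 0L, relab)
  prov <- prov |>
    dplyr::filter(.data$pgd_id %in% survivors) |>
    dplyr::mutate(pgd_id = match(.data$pgd_id, survivors),
                  n_cells = as.integer(tabulate(lab[lab > 0L],
                                                length(survivors))[.data$pgd_id]))
  new_pgd_map(label_grid(sp, matrix(lab, sp$n_rows)), prov, log)
}

#' Summarize a PGD map
#'
#' @param pgd A `pgd_map`.
#' @return A tibble with one row per PGD: `pgd_id`, `zone_id`, `combo`,
#'   `n_cells`, and `area` (`n_cells * cell_size^2`, map units squared).
#'   Cell counts sum to the size of the land mask.
#' @export
pgd_summary <- function(pgd) {
  stopifnot(inherits(pgd, "pgd_map"))
  pgd$provenance |>
    dplyr::mutate(area = .data$n_cells * pgd$zones$spec$cell_size^2)
}

#' @export
print.pgd_map <- function(x, ...) {
  cat(sprintf("<pgd_map> %s, %d proxies of genetic differentiation over %d life zones\n",
              format(x$zones$spec), nrow(x$provenance),
              dplyr::n_distinct(x$provenance$zone_id)))
  invisible(x)
}

#' @export
tidy.pgd_map <- function(x, ...) {
  tidy(x$zones) |>
    dplyr::rename(pgd_id = "value") |>
    dplyr::left_join(dplyr::select(x$provenance, "pgd_id", "zone_id", "combo"),
                     by = "pgd_id")
}

#' @export
glance.pgd_map <- function(x, ...) {
  tibble::tibble(
    n_pgd = nrow(x$provenance),
    n_zones = dplyr::n_distinct(x$provenance$zone_id),
    n_cells = sum(x$provenance$n_cells),
    median_cells = stats::median(x$provenance$n_cells)
  )
}
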