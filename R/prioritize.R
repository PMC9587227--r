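#' Ranking configuration
#'
#' Options of the greedy core-area removal: `warp` cells are removed per
#' recomputation batch (1 = exact single-cell greedy), ties in the marginal
#' loss are broken by lowest linear cell index (reproducible default) or by
#' a seeded random permutation, and `use_conditions` toggles multiplication
#' of feature values by their linked habitat-condition layers.
#'
#' @param warp Cells removed per batch, >= 1.
#' @param tie_break `"lowest-index"` or `"seeded-random"`.
#' @param seed Integer seed for the random tie-break.
#' @param use_conditions Logical.
#' @return An object of class `rank_config`.
#' @export
rank_config <- function(warp = 1, tie_break = c("lowest-index", "seeded-random"),
                        seed = 1L, use_conditions = TRUE) {
  tie_break <- match.arg(tie_break)
  if (warp < 1) rlang::abort("warp must be >= 1", class = "pgdplan_error_rank")
  structure(list(warp = as.integer(warp), tie_break = tie_break,
                 seed = as.integer(seed), use_conditions = use_conditions),
            class = "rank_config")
}

# Core greedy removal. feat_cells/feat_vals: per-feature cell indices and
# effective values; w: weights (0 = evaluation-only, skipped); land: linear
# indices of rankable cells. Returns land cells in removal order together
# with the marginal loss at removal.
caz_order <- function(feat_cells, feat_vals, w, land, n_total, warp = 1L,
                      tie_rand = NULL) {
  n <- length(land)
  nf <- length(feat_cells)
  in_land <- logical(n_total)
  in_land[land] <- TRUE
  # restrict features to the rankable mask; Q is the remaining total there
  for (j in seq_len(nf)) {
    keep <- in_land[feat_cells[[j]]]
    feat_cells[[j]] <- feat_cells[[j]][keep]
    feat_vals[[j]] <- feat_vals[[j]][keep]
  }
  active <- which(w > 0 & lengths(feat_cells) > 0)
  Q <- vapply(seq_len(nf), function(j) sum(feat_vals[[j]]), numeric(1))
  cf_idx <- vector("list", n_total)
  cf_val <- vector("list", n_total)
  for (j in active) {
    cs <- feat_cells[[j]]
    vs <- feat_vals[[j]]
    for (k in seq_along(cs)) {
      cc <- cs[k]
      cf_idx[[cc]] <- c(cf_idx[[cc]], j)
      cf_val[[cc]] <- c(cf_val[[cc]], vs[k])
    }
  }
  ratio <- ifelse(Q > 0, w / Q, 0)
  delta_of <- function(cc) {
    js <- cf_idx[[cc]]
    if (is.null(js)) return(0)
    m <- max(ratio[js] * cf_val[[cc]])
    if (m > 0) m else 0
  }
  delta <- rep(Inf, length(in_land))
  delta[land] <- vapply(land, delta_of, numeric(1))
  retained <- logical(length(in_land))
  retained[land] <- TRUE
  order_out <- integer(n)
  delta_out <- numeric(n)
  done <- 0L
  while (done < n) {
    take <- min(warp, n - done)
    cand <- which(retained)
    d <- delta[cand]
    ord <- if (is.null(tie_rand)) order(d) else order(d, tie_rand[cand])
    batch <- cand[ord[seq_len(take)]]
    dirty_feats <- integer(0)
    for (cc in batch) {
      retained[cc] <- FALSE
      done <- done + 1L
      order_out[done] <- cc
      delta_out[done] <- delta[cc]
      js <- cf_idx[[cc]]
      if (!is.null(js)) {
        vs <- cf_val[[cc]]
        Q[js] <- Q[js] - vs
        dirty_feats <- c(dirty_feats, js)
      }
    }
    if (done >= n) break
    dirty_feats <- unique(dirty_feats)
    if (length(dirty_feats) > 0) {
      ratio[dirty_feats] <- ifelse(Q[dirty_feats] > 1e-12,
                                   w[dirty_feats] / Q[dirty_feats], 0)
      dirty <- unique(unlist(feat_cells[dirty_feats]))
      dirty <- dirty[retained[dirty]]
      if (length(dirty) > 0) {
        delta[dirty] <- vapply(dirty, delta_of, numeric(1))
      }
    }
  }
  list(order = order_out, delta = delta_out)
}

effective_features <- function(features, conditions, use_conditions) {
  purrr::map(features$features, function(f) {
    v <- f$values
    if (use_conditions && f$kind == "raster" && !is.na(f$condition) &&
        !is.null(conditions[[f$condition]])) {
      cond <- as.vector(conditions[[f$condition]]$values)[f$cells]
      cond[is.na(cond)] <- 1 # no land-cover information: leave value as is
      v <- v * cond
    }
    list(cells = f$cells, values = v, weight = f$weight)
  })
}

#' Core-area zonation ranking
#'
#' Ranks every land cell by iterative greedy removal under the core-area
#' zonation (CAZ) rule: at each step the cell with the smallest marginal
#' loss `delta_i = max_j w_j * v'_ij / Q_j` is removed, where `v'_ij` is
#' feature j's (condition-weighted) value in cell i, `Q_j` its remaining
#' total over the retained cells, and `w_j` its weight. The rule protects,
#' at every step, the cell most important for its worst-off feature, so
#' core areas of every feature survive to the top fractions. Features with
#' weight 0 never enter the loss but remain available for evaluation;
#' exhausted features (`Q_j = 0`) are skipped. Cell cost is uniform.
#'
#' @param features A `feature_set` with at least one positively weighted,
#'   non-empty feature.
#' @param conditions Optional named list (by taxon) of habitat-condition
#'   [value_grid()]s; applied to condition-linked raster features when
#'   `config$use_conditions` is `TRUE`.
#' @param config A [rank_config()].
#' @param mask Optional [label_grid()]; its positive cells define the
#'   rankable land mask. Default: the union of all feature cells.
#' @return An object of class `priority_rank_map`: `rank` (a [value_grid()]
#'   with values in `(0, 1]`, the fraction of land removed at or before each
#'   cell; higher = retained longer = higher priority), `removal_log` (tibble
#'   `step`, `cell`, `row`, `col`, `delta`), and `n_land`.
#' @export
caz_rank <- function(features, conditions = NULL, config = rank_config(),
                     mask = NULL) {
  stopifnot(inherits(features, "feature_set"), inherits(config, "rank_config"))
  eff <- effective_features(features, conditions, config$use_conditions)
  w <- purrr::map_dbl(eff, "weight")
  feat_cells <- purrr::map(eff, "cells")
  feat_vals <- purrr::map(eff, "values")
  if (all(lengths(feat_cells) == 0)) {
    rlang::abort("all features are empty", class = "pgdplan_error_rank")
  }
  if (!any(w > 0)) {
    rlang::abort("need at least one feature with positive weight",
                 class = "pgdplan_error_rank")
  }
  land <- if (is.null(mask)) {
    sort(unique(unlist(feat_cells)))
  } else {
    which(as.vector(mask$labels) > 0L)
  }
  tie_rand <- NULL
  if (config$tie_break == "seeded-random") {
    tie_rand <- numeric(n_cells(features$spec))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed)
    tie_rand[] <- runif(length(tie_rand))
  }
  res <- caz_order(feat_cells, feat_vals, w, land,
                   n_total = n_cells(features$spec), warp = config$warp,
                   tie_rand = tie_rand)
  build_rank_map(res$order, res$delta, features$spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

build_rank_map <- function(order, delta, spec) {
  n <- length(order)
  rank <- rep(NA_real_, n_cells(spec))
  rank[order] <- seq_len(n) / n
  rows <- (order - 1L) %% spec$n_rows + 1L
  cols <- (order - 1L) %/% spec$n_rows + 1L
  structure(
    list(
      rank = value_grid(spec, matrix(rank, spec$n_rows)),
      removal_log = tibble::tibble(step = seq_len(n), cell = order,
                                   row = rows, col = cols, delta = delta),
      n_land = n
    ),
    class = "priority_rank_map"
  )
}

#' @export
print.priority_rank_map <- function(x, ...) {
  cat(sprintf("<priority_rank_map> %s, %d land cells ranked\n",
              format(x$rank$spec), x$n_land))
  invisible(x)
}

#' @export
tidy.priority_rank_map <- function(x, ...) {
  tidy(x$rank) |> dplyr::rename(rank = "value")
}

#' @export
glance.priority_rank_map <- function(x, ...) {
  tibble::tibble(n_land = x$n_land,
                 n_cells = n_cells(x$rank$spec),
                 max_delta = max(x$removal_log$delta))
}

#' Planning-unit (ADMU) ranking
#'
#' Runs [caz_rank()] independently inside each planning unit (each PGD used
#' as an administrative unit), then interleaves the units by within-unit
#' rank quantile: a cell's global rank is its within-unit quantile, with
#' ties across units broken by unit id. At every top fraction f each unit
#' therefore contributes approximately f of its own area (up to one-cell
#' quantization), guaranteeing representation inside every unit. This is a
#' quantile-interleave reading of Zonation's administrative-units mode.
#'
#' @param features A `feature_set` (features are restricted to each unit;
#'   remaining totals `Q_j` are computed within the unit).
#' @param units A `pgd_map` whose zones partition the land mask. Units with
#'   zero land cells are skipped with a log entry.
#' @inheritParams caz_rank
#' @return A `priority_rank_map` over the union of the units.
#' @export
admu_rank <- function(features, units, conditions = NULL,
                      config = rank_config()) {
  stopifnot(inherits(features, "feature_set"), inherits(units, "pgd_map"))
  eff <- effective_features(features, conditions, config$use_conditions)
  w <- purrr::map_dbl(eff, "weight")
  zl <- as.vector(units$zones$labels)
  unit_ids <- units$provenance$pgd_id
  per_unit <- list()
  skipped <- character(0)
  for (u in unit_ids) {
    land_u <- which(zl == u)
    if (length(land_u) == 0) {
      skipped <- c(skipped, sprintf("unit %d has no land cells; skipped", u))
      next
    }
    res <- caz_order(purrr::map(eff, "cells"), purrr::map(eff, "values"),
                     w, land_u, n_total = n_cells(units$zones$spec),
                     warp = config$warp)
    per_unit[[length(per_unit) + 1]] <- tibble::tibble(
      cell = res$order, delta = res$delta, unit = u,
      quantile = seq_along(res$order) / length(res$order)
    )
  }
  if (length(per_unit) == 0) {
    rlang::abort("no unit has land cells", class = "pgdplan_error_rank")
  }
  all <- dplyr::bind_rows(per_unit) |>
    dplyr::arrange(.data$quantile, .data$unit)
  out <- build_rank_map(all$cell, all$delta, features$spec)
  out$log <- skipped
  out
}

#' Top landscape fraction
#'
#' The binary mask of the highest-priority fraction `f` of the land: cells
#' with rank greater than `1 - f`. Masks are nested: the top 10% lies inside
#' the top 20%, which lies inside the top 30%.
#'
#' @param rank A `priority_rank_map`.
#' @param f Fraction in `[0, 1]`.
#' @return A [label_grid()] with 1 on selected cells, 0 elsewhere.
#' @export
top_fraction <- function(rank, f) {
  stopifnot(inherits(rank, "priority_rank_map"))
  if (!is.finite(f) || f < 0 || f > 1) {
    rlang::abort("f must be in [0, 1]", class = "pgdplan_error_rank")
  }
  r <- as.vector(rank$rank$values)
  sel <- !is.na(r) & r > 1 - f
  label_grid(rank$rank$spec,
             matrix(as.integer(sel), rank$rank$spec$n_rows))
}
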