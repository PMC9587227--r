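#' Representation curves
#'
#' For every feature, the retained proportion `rep_j(f)` of its total
#' (condition-weighted, when conditions were applied in the ranking) value
#' as a function of the retained top landscape fraction `f`, evaluated at
#' every removal step (or a stride of steps). Curves start at `rep(0) = 0`,
#' end at `rep(1) = 1`, and are non-decreasing. A feature whose total is
#' zero is reported with `NA` (undefined), never silently as 0.
#'
#' @param rank A `priority_rank_map`.
#' @param features A `feature_set` on the same grid.
#' @param conditions Optional named condition grids, matched to how the
#'   ranking was run.
#' @param use_conditions Logical; apply `conditions` to linked features.
#' @param stride Evaluate every `stride`-th removal step (plus the two
#'   endpoints); default 1 = every step.
#' @return A tibble of class `representation_curves` with columns
#'   `feature_id`, `taxon`, `pgd_id`, `f`, `rep`.
#' @export
representation_curves <- function(rank, features, conditions = NULL,
                                  use_conditions = TRUE, stride = 1L) {
  stopifnot(inherits(rank, "priority_rank_map"),
            inherits(features, "feature_set"))
  bad <- spec_equal_fields(rank$rank$spec, features$spec)
  if (length(bad) > 0) {
    rlang::abort(paste0("rank map and features are not aligned: ",
                        paste(bad, collapse = ", ")),
                 class = "pgdplan_error_alignment")
  }
  eff <- effective_features(features, conditions, use_conditions)
  meta <- features_meta(features)
  n <- rank$n_land
  rankvec <- as.vector(rank$rank$values)
  fs <- unique(c(0, seq_len(n)[seq_len(n) %% stride == 0] / n, 1))
  fs <- sort(fs)
  curves <- purrr::map_dfr(seq_along(eff), function(j) {
    f <- eff[[j]]
    total <- sum(f$values)
    if (total == 0) {
      return(tibble::tibble(feature_id = meta$feature_id[j],
                            taxon = meta$taxon[j], pgd_id = meta$pgd_id[j],
                            f = fs, rep = NA_real_))
    }
    r <- rankvec[f$cells]
    # retained at top fraction fr: cells with rank > 1 - fr
    ord <- order(r, decreasing = TRUE)
    cum <- cumsum(f$values[ord])
    ranks_sorted <- r[ord]
    rep_at <- vapply(fs, function(fr) {
      k <- sum(ranks_sorted > 1 - fr, na.rm = TRUE)
      if (k == 0) 0 else cum[k] / total
    }, numeric(1))
    tibble::tibble(feature_id = meta$feature_id[j], taxon = meta$taxon[j],
                   pgd_id = meta$pgd_id[j], f = fs, rep = rep_at)
  })
  structure(curves, class = c("representation_curves", class(curves)))
}

#' Mean PGD representation per taxon
#'
#' For each taxon, the unweighted mean over its non-empty zone-layers
#' (taxon x PGD features) of the retained proportion at top fraction `f`;
#' a taxon with a single layer returns that layer's value, and taxa with no
#' layers are excluded (listed in the `excluded` attribute). Optionally
#' joined to IUCN categories for grouping.
#'
#' @param curves A `representation_curves` tibble.
#' @param features The `feature_set` the curves came from.
#' @param f Top fraction at which to evaluate.
#' @param taxa Optional taxon table with `taxon` and `iucn` columns.
#' @return A tibble with columns `taxon`, `n_layers`, `mean_rep` (and
#'   `iucn` when `taxa` is supplied).
#' @export
taxon_mean_pgd_representation <- function(curves, features, f, taxa = NULL) {
  meta <- features_meta(features)
  zone_layers <- meta$feature_id[meta$pgd_id > 0 & !is.na(meta$taxon)]
  at_f <- curves |>
    dplyr::filter(.data$feature_id %in% zone_layers) |>
    dplyr::group_by(.data$feature_id, .data$taxon) |>
    dplyr::summarise(rep = rep_at_fraction(.data$f, .data$rep, !!f),
                     .groups = "drop")
  out <- at_f |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(n_layers = dplyr::n(), mean_rep = mean(.data$rep),
                     .groups = "drop")
  all_taxa <- unique(meta$taxon[!is.na(meta$taxon)])
  excluded <- setdiff(all_taxa, out$taxon)
  if (!is.null(taxa)) {
    out <- dplyr::left_join(out, dplyr::select(taxa, "taxon", "iucn"),
                            by = "taxon")
  }
  attr(out, "excluded") <- excluded
  out
}

# value of a step-sampled curve at fraction f. rep(f) counts cells with
# rank > 1 - f, which is constant on ((k-1)/N, k/N], so the matching sample
# is the smallest sampled fraction >= f (left-continuous step lookup).
rep_at_fraction <- function(fs, reps, f) {
  ord <- order(fs)
  fs <- fs[ord]
  reps <- reps[ord]
  ok <- which(fs >= f - 1e-12)
  if (length(ok) == 0) return(reps[length(reps)])
  reps[min(ok)]
}

#' Per-PGD representation of one distribution at a threshold mask
#'
#' For each PGD overlapping a taxon's binary distribution, the proportion of
#' the distribution-within-PGD area covered by the mask:
#' `|SDM & pgd & mask| / |SDM & pgd|`. PGDs with empty intersection are
#' omitted.
#'
#' @param mask Binary [label_grid()] (e.g. from [top_fraction()]).
#' @param sdm Binary [value_grid()] distribution.
#' @param pgd A `pgd_map`.
#' @return Tibble with `pgd_id`, `n_cells`, `n_retained`, `proportion`.
#' @export
pgd_area_representation <- function(mask, sdm, pgd) {
  check_alignment(mask, sdm, pgd$zones)
  pos <- grid_positive_cells(sdm)
  zl <- as.vector(pgd$zones$labels)[pos]
  sel <- as.vector(mask$labels)[pos] > 0L
  keep <- zl > 0L
  tibble::tibble(pgd_id = zl[keep], retained = sel[keep]) |>
    dplyr::group_by(.data$pgd_id) |>
    dplyr::summarise(n_cells = dplyr::n(), n_retained = sum(.data$retained),
                     proportion = mean(.data$retained), .groups = "drop")
}

#' Overlay statistics of a mask against reference layers
#'
#' The proportion of the mask covered by each reference layer:
#' `|mask & layer| / |mask|` (e.g. the share of a proposed conservation area
#' lying inside federal protected areas).
#'
#' @param mask Binary [label_grid()]; must be non-empty.
#' @param layers Named list of binary [label_grid()]s.
#' @return Tibble with `layer`, `n_mask`, `n_overlap`, `proportion`.
#' @export
overlay_stats <- function(mask, layers) {
  check_alignment(c(list(mask), unname(layers)))
  m <- as.vector(mask$labels) > 0L
  if (!any(m)) {
    rlang::abort("mask is empty", class = "pgdplan_error_evaluate")
  }
  purrr::imap_dfr(layers, function(l, nm) {
    ov <- sum(as.vector(l$labels)[m] > 0L)
    tibble::tibble(layer = nm, n_mask = sum(m), n_overlap = ov,
                   proportion = ov / sum(m))
  })
}

#' Assign genetic samples to PGDs by buffer majority
#'
#' Assigns each sampling locality to the PGD label most frequent among the
#' cells whose centres lie within `radius` of the point (the buffer rule
#' used to link genomic sampling localities to proxies; 5 km on a metric
#' grid is `radius = 5000`). Ties go to the smallest PGD id; `radius = 0`
#' degenerates to the containing cell's label; localities whose buffer
#' contains no labelled cell are flagged unassigned (`NA`).
#'
#' @param samples Tibble with `x`, `y` (map units) and any other columns
#'   (e.g. cluster memberships).
#' @param pgd A `pgd_map`.
#' @param radius Buffer radius in map units, >= 0.
#' @return `samples` with an added integer `pgd_id` column.
#' @export
assign_samples_to_pgd <- function(samples, pgd, radius) {
  stopifnot(inherits(pgd, "pgd_map"), radius >= 0)
  samples <- tibble::as_tibble(samples)
  if (any(!is.finite(samples$x)) || any(!is.finite(samples$y))) {
    rlang::abort("sample coordinates must be finite", class = "pgdplan_error_points")
  }
  sp <- pgd$zones$spec
  lab <- pgd$zones$labels
  s <- sp$cell_size
  reach <- ceiling(radius / s)
  assigned <- purrr::map2_int(samples$x, samples$y, function(px, py) {
    pt <- points_to_cells(tibble::tibble(x = px, y = py), sp)
    if (reach == 0) {
      if (pt$outside) return(NA_integer_)
      l <- lab[pt$row, pt$col]
      return(if (l == 0L) NA_integer_ else l)
    }
    # candidate window, then exact centre-distance test
    c0 <- floor((px - sp$origin_x) / s) + 1
    r0 <- floor((sp$origin_y - py) / s) + 1
    rows <- max(1, r0 - reach):min(sp$n_rows, r0 + reach)
    cols <- max(1, c0 - reach):min(sp$n_cols, c0 + reach)
    if (length(rows) == 0 || length(cols) == 0) return(NA_integer_)
    cx <- sp$origin_x + (cols - 0.5) * s
    cy <- sp$origin_y - (rows - 0.5) * s
    dist2 <- outer((cy - py)^2, (cx - px)^2, `+`)
    labs <- lab[rows, cols, drop = FALSE][dist2 <= radius^2]
    labs <- labs[labs > 0L]
    if (length(labs) == 0) return(NA_integer_)
    counts <- table(labs)
    winners <- as.integer(names(counts)[counts == max(counts)])
    min(winners)
  })
  dplyr::mutate(samples, pgd_id = assigned)
}

#' Cross-tabulate dominant genetic clusters against PGDs
#'
#' Reduces each sample's admixture membership vector to its dominant cluster
#' (argmax, ties to the smallest cluster index), cross-tabulates dominant
#' cluster against assigned PGD, and summarizes the agreement of the two
#' partitions with the adjusted Rand index computed from the contingency
#' table by its standard closed form. Unassigned samples are excluded and
#' counted.
#'
#' @param samples Tibble with a `pgd_id` column (see
#'   [assign_samples_to_pgd()]) and membership columns `cluster_1`,
#'   `cluster_2`, ... (proportions summing to 1 per row).
#' @return A list with `table` (contingency matrix, clusters x PGDs), `ari`
#'   (adjusted Rand index), `n_used`, and `n_unassigned`.
#' @export
cluster_zone_crosstab <- function(samples) {
  mcols <- grep("^cluster_", names(samples), value = TRUE)
  if (length(mcols) == 0) {
    rlang::abort("samples need membership columns cluster_1, cluster_2, ...",
                 class = "pgdplan_error_evaluate")
  }
  memb <- as.matrix(samples[, mcols])
  sums <- rowSums(memb)
  if (any(memb < 0) || any(abs(sums - 1) > 1e-9)) {
    rlang::abort("membership rows must be non-negative and sum to 1",
                 class = "pgdplan_error_evaluate")
  }
  dominant <- apply(memb, 1, which.max) # which.max takes the first of ties
  used <- !is.na(samples$pgd_id)
  tab <- table(cluster = dominant[used], pgd = samples$pgd_id[used])
  list(table = tab, ari = adjusted_rand_index(tab),
       n_used = sum(used), n_unassigned = sum(!used))
}

#' Adjusted Rand index from a contingency table
#'
#' The chance-corrected agreement between two partitions, from the standard
#' closed form over pair counts: `(sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. Returns 0 for degenerate
#' tables where the correction denominator vanishes (e.g. a single cluster).
#'
#' @param tab A contingency matrix of counts.
#' @return The adjusted Rand index, a number <= 1.
#' @export
adjusted_rand_index <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  a <- sum(ch2(rowSums(tab)))
  b <- sum(ch2(colSums(tab)))
  expected <- a * b / ch2(n)
  maxi <- (a + b) / 2
  if (abs(maxi - expected) < 1e-12) return(0)
  (sum_ij - expected) / (maxi - expected)
}
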