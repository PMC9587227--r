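#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' objects: grids as raster tiles, life-zone and PGD maps as categorical
#' mosaics, priority rank maps with a viridis-style gradient, and
#' representation curves as step lines per feature.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pgdplan-autoplot
NULL

#' @rdname pgdplan-autoplot
#' @export
autoplot.value_grid <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname pgdplan-autoplot
#' @export
autoplot.label_grid <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(value = factor(ifelse(.data$value == 0, NA, .data$value))) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "label")
}

#' @rdname pgdplan-autoplot
#' @export
autoplot.life_zone_map <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(name = ifelse(.data$zone_id == 0, NA, .data$name)) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$name)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "life zone")
}

#' @rdname pgdplan-autoplot
#' @export
autoplot.pgd_map <- function(object, ...) {
  autoplot(object$zones) + ggplot2::labs(fill = "PGD")
}

#' @rdname pgdplan-autoplot
#' @export
autoplot.priority_rank_map <- function(object, ...) {
  autoplot(object$rank) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(fill = "priority rank")
}

#' @rdname pgdplan-autoplot
#' @export
autoplot.representation_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$f, .data$rep,
                                       group = .data$feature_id)) +
    ggplot2::geom_step(alpha = 0.4) +
    ggplot2::labs(x = "top landscape fraction", y = "proportion represented")
}

#' Mean representation-curve summary
#'
#' Averages representation curves over features (optionally within groups,
#' e.g. per taxon or scenario) on a common fraction grid, the form in which
#' scenario performance is usually compared.
#'
#' @param curves A `representation_curves` tibble.
#' @param at Fractions at which to evaluate (default every 0.01).
#' @return A tibble with `f` and `mean_rep`.
#' @export
mean_curve <- function(curves, at = seq(0, 1, by = 0.01)) {
  curves |>
    dplyr::filter(!is.na(.data$rep)) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::reframe(fr = at, rep_fr = vapply(at, function(x)
      rep_at_fraction(.data$f, .data$rep, x), numeric(1))) |>
    dplyr::group_by(f = .data$fr) |>
    dplyr::summarise(mean_rep = mean(.data$rep_fr), .groups = "drop")
}
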