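#' Grid specification
#'
#' A `grid_spec` describes a planar, uniformly spaced raster grid: its shape,
#' the map coordinate of the top-left corner, the (square) cell size, a
#' free-text CRS identifier, and the nodata sentinel used on disk. Two grids
#' can enter the same analysis only if their specs are equal in every field;
#' no resampling or reprojection is ever performed (see [check_alignment()]).
#'
#' Cell extents are half-open: cell `(r, c)` covers
#' `[x0 + (c-1)s, x0 + c*s)` in x and `(y0 - r*s, y0 - (r-1)*s]` in y,
#' where `(x0, y0)` is the top-left corner and `s` the cell size. Row 1 is the
#' top row. All area statistics in the package are cell counts times
#' `cell_size^2`.
#'
#' @param n_rows,n_cols Grid shape, positive integers.
#' @param origin_x,origin_y Map coordinates of the top-left grid corner.
#' @param cell_size Side length of the square cells, in map units (> 0).
#' @param crs_id Free-text identifier of the coordinate reference system.
#' @param nodata Sentinel value written to file for missing cells.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(3, 4, 0, 3000, 1000)
#' @export
grid_spec <- function(n_rows, n_cols, origin_x = 0, origin_y = n_rows * cell_size,
                      cell_size = 1, crs_id = "unknown", nodata = -9999) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_size) == 1)
  if (n_rows < 1 || n_cols < 1) {
    rlang::abort("n_rows and n_cols must be >= 1", class = "pgdplan_error_spec")
  }
  if (!is.finite(cell_size) || cell_size <= 0) {
    rlang::abort("cell_size must be a positive finite number",
                 class = "pgdplan_error_spec")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size), crs_id = as.character(crs_id),
      nodata = as.numeric(nodata)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells, cell_size %g, origin (%g, %g), crs '%s', nodata %g\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_id, x$nodata
  ))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d @ %g", x$n_rows, x$n_cols, x$cell_size)
}

n_cells <- function(spec) spec$n_rows * spec$n_cols

spec_equal_fields <- function(a, b) {
  fields <- c("n_rows", "n_cols", "origin_x", "origin_y", "cell_size", "crs_id")
  fields[!purrr::map_lgl(fields, function(f) isTRUE(all.equal(a[[f]], b[[f]])))]
}

#' Value and label grids
#'
#' `value_grid()` wraps a numeric matrix (reals, `NA` for nodata) together
#' with a [grid_spec()]; `label_grid()` wraps a non-negative integer matrix
#' where label 0 is reserved for nodata / outside-mask cells. These are the
#' two raster containers every other module consumes.
#'
#' @param spec A [grid_spec()]. Its shape must match the matrix.
#' @param values Numeric matrix (`n_rows` x `n_cols`); `NA` marks nodata.
#' @param labels Integer matrix (`n_rows` x `n_cols`); 0 marks nodata.
#' @return An object of class `value_grid` or `label_grid`.
#' @examples
#' sp <- grid_spec(2, 2)
#' value_grid(sp, matrix(1:4, 2, 2))
#' label_grid(sp, matrix(c(1L, 1L, 0L, 2L), 2, 2))
#' @export
value_grid <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!identical(dim(values), c(spec$n_rows, spec$n_cols))) {
    rlang::abort("values shape does not match spec", class = "pgdplan_error_shape")
  }
  if (any(is.infinite(values))) {
    rlang::abort("values must be finite outside nodata",
                 class = "pgdplan_error_values")
  }
  structure(list(spec = spec, values = values), class = "value_grid")
}

#' @rdname value_grid
#' @export
label_grid <- function(spec, labels) {
  stopifnot(inherits(spec, "grid_spec"))
  labels <- as.matrix(labels)
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels))) {
    rlang::abort("labels must be non-negative integers (0 = nodata)",
                 class = "pgdplan_error_values")
  }
  storage.mode(labels) <- "integer"
  if (!identical(dim(labels), c(spec$n_rows, spec$n_cols))) {
    rlang::abort("labels shape does not match spec", class = "pgdplan_error_shape")
  }
  structure(list(spec = spec, labels = labels), class = "label_grid")
}

#' @export
print.value_grid <- function(x, ...) {
  cat(sprintf("<value_grid> %s, %d nodata cells, range [%g, %g]\n",
              format(x$spec), sum(is.na(x$values)),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' @export
print.label_grid <- function(x, ...) {
  labs <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<label_grid> %s, %d labels, %d masked cells\n",
              format(x$spec), length(labs), sum(x$labels == 0L)))
  invisible(x)
}

grid_data <- function(g) if (inherits(g, "label_grid")) g$labels else g$values

#' Convert a grid to a long tibble
#'
#' One row per cell with row/col indices, cell-centre map coordinates and the
#' cell value (or label). Nodata cells are kept with `NA` value (value grids)
#' or label 0 (label grids) so the tibble always has `n_rows * n_cols` rows.
#'
#' @param x A `value_grid` or `label_grid`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @export
tidy.value_grid <- function(x, ...) {
  sp <- x$spec
  tibble::tibble(
    row = rep(seq_len(sp$n_rows), times = sp$n_cols),
    col = rep(seq_len(sp$n_cols), each = sp$n_rows),
    value = as.vector(grid_data(x))
  ) |>
    dplyr::mutate(
      x = sp$origin_x + (.data$col - 0.5) * sp$cell_size,
      y = sp$origin_y - (.data$row - 0.5) * sp$cell_size,
      .before = "value"
    )
}

#' @rdname tidy.value_grid
#' @export
tidy.label_grid <- tidy.value_grid
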