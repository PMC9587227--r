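#' Read and write rasters as ESRI ASCII grids
#'
#' Rasters are stored in the ESRI ASCII grid format (`.asc`): a six-line
#' georeference header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by the cell values, top row first.
#' The format is single-band by construction and round-trips every grid the
#' package produces bit-for-bit at full double precision. The CRS identifier,
#' which the ASCII grid header cannot carry, is written to a one-line sidecar
#' file `<path>.crs`; a missing sidecar reads back as `"unknown"`.
#'
#' @param path Path to the `.asc` file.
#' @param kind `"value"` (real-valued, nodata -> `NA`) or `"label"`
#'   (non-negative integers, nodata -> 0).
#' @return `read_grid()` returns a [value_grid()] or [label_grid()];
#'   `write_grid()` returns `path` invisibly.
#' @examples
#' g <- value_grid(grid_spec(2, 2), matrix(1:4, 2, 2))
#' p <- tempfile(fileext = ".asc")
#' write_grid(g, p)
#' read_grid(p, "value")
#' @export
read_grid <- function(path, kind = c("value", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    rlang::abort(paste0("cannot read raster: no such file '", path, "'"),
                 class = "pgdplan_error_io")
  }
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) {
                      rlang::abort(paste0("cannot read raster '", path, "'"),
                                   class = "pgdplan_error_io", parent = e)
                    })
  header <- list()
  body_start <- NA_integer_
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i],
                    regexec("^\\s*([A-Za-z_]+)\\s+(-?[0-9.eE+-]+)\\s*$", lines[i]))[[1]]
    if (length(m) == 3) {
      header[[tolower(m[2])]] <- as.numeric(m[3])
    } else {
      body_start <- i
      break
    }
  }
  if (is.na(body_start)) {
    rlang::abort(paste0("raster '", path, "' has no data rows"),
                 class = "pgdplan_error_io")
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(needed, names(header))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing georeference in '", path, "': header lacks ",
             paste(missing, collapse = ", ")),
      class = "pgdplan_error_georef"
    )
  }
  nodata <- header[["nodata_value"]] %||% -9999
  nr <- as.integer(header$nrows)
  nc <- as.integer(header$ncols)
  vals <- suppressWarnings(as.numeric(scan(
    text = paste(lines[seq(body_start, length(lines))], collapse = "\n"),
    what = double(), quiet = TRUE
  )))
  if (length(vals) != nr * nc) {
    rlang::abort(
      sprintf(
        "raster '%s' is not single-band: %d values for a %d x %d grid",
        path, length(vals), nr, nc
      ),
      class = "pgdplan_error_band"
    )
  }
  crs_path <- paste0(path, ".crs")
  crs_id <- if (file.exists(crs_path)) trimws(readLines(crs_path, warn = FALSE)[1]) else "unknown"
  spec <- grid_spec(
    n_rows = nr, n_cols = nc,
    origin_x = header$xllcorner,
    origin_y = header$yllcorner + nr * header$cellsize,
    cell_size = header$cellsize, crs_id = crs_id, nodata = nodata
  )
  mat <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (kind == "value") {
    mat[mat == nodata] <- NA_real_
    value_grid(spec, mat)
  } else {
    mat[mat == nodata] <- 0
    label_grid(spec, mat)
  }
}

#' @param grid A [value_grid()] or [label_grid()] to write.
#' @rdname read_grid
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, c("value_grid", "label_grid")))
  sp <- grid$spec
  mat <- grid_data(grid)
  if (inherits(grid, "value_grid")) {
    mat[is.na(mat)] <- sp$nodata
  } else {
    mat[mat == 0L] <- as.integer(sp$nodata)
  }
  header <- c(
    sprintf("ncols %d", sp$n_cols),
    sprintf("nrows %d", sp$n_rows),
    sprintf("xllcorner %.10g", sp$origin_x),
    sprintf("yllcorner %.10g", sp$origin_y - sp$n_rows * sp$cell_size),
    sprintf("cellsize %.10g", sp$cell_size),
    sprintf("NODATA_value %.10g", sp$nodata)
  )
  rows <- apply(mat, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(header, rows), path)
  if (!identical(sp$crs_id, "unknown")) {
    writeLines(sp$crs_id, paste0(path, ".crs"))
  }
  invisible(path)
}

#' Check that grids share one analysis grid
#'
#' Verifies that every supplied grid has an identical [grid_spec()] (shape,
#' origin, cell size, CRS). The package never resamples: misaligned inputs
#' are a hard error naming the first offending field.
#'
#' @param ... Grids (`value_grid`/`label_grid`), or a single list of them.
#' @return The shared `grid_spec`, invisibly.
#' @export
check_alignment <- function(...) {
  grids <- rlang::list2(...)
  if (length(grids) == 1 && !inherits(grids[[1]], c("value_grid", "label_grid"))) {
    grids <- grids[[1]]
  }
  if (length(grids) < 1) {
    rlang::abort("need at least one grid", class = "pgdplan_error_alignment")
  }
  ref <- grids[[1]]$spec
  for (i in seq_along(grids)[-1]) {
    bad <- spec_equal_fields(ref, grids[[i]]$spec)
    if (length(bad) > 0) {
      rlang::abort(
        sprintf("grids are not aligned: grid %d differs in %s", i,
                paste(bad, collapse = ", ")),
        class = "pgdplan_error_alignment"
      )
    }
  }
  invisible(ref)
}

#' Map points to grid cells
#'
#' Assigns each point to the cell whose half-open extent contains it: cell
#' `(r, c)` covers `[x0 + (c-1)s, x0 + c*s)` in x (left edge inclusive) and
#' `(y0 - r*s, y0 - (r-1)*s]` in y (top edge inclusive). Points outside the
#' grid are flagged, never dropped, so every input row yields exactly one
#' output row.
#'
#' @param points A data frame with numeric columns `x` and `y` (map units);
#'   other columns are carried through.
#' @param spec A [grid_spec()].
#' @return The input as a tibble with integer columns `row`, `col` (`NA` when
#'   outside), `cell` (linear index, column-major) and logical `outside`.
#' @examples
#' pts <- tibble::tibble(id = "a", x = 1500, y = 2500)
#' points_to_cells(pts, grid_spec(3, 3, 0, 3000, 1000))
#' @export
points_to_cells <- function(points, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  points <- tibble::as_tibble(points)
  if (!all(c("x", "y") %in% names(points))) {
    rlang::abort("points must have columns x and y", class = "pgdplan_error_points")
  }
  if (any(!is.finite(points$x)) || any(!is.finite(points$y))) {
    rlang::abort("point coordinates must be finite", class = "pgdplan_error_points")
  }
  s <- spec$cell_size
  col <- floor((points$x - spec$origin_x) / s) + 1
  dy <- (spec$origin_y - points$y) / s
  row <- floor(dy) + 1
  # top edge inclusive: a point exactly on an interior horizontal edge
  # belongs to the cell below it, which floor()+1 already gives; the grid's
  # own top edge (dy == 0) must still land in row 1
  outside <- col < 1 | col > spec$n_cols | row > spec$n_rows | dy < 0
  row <- as.integer(ifelse(outside, NA, row))
  col <- as.integer(ifelse(outside, NA, col))
  points |>
    dplyr::mutate(
      row = row, col = col,
      cell = as.integer(row + (col - 1L) * spec$n_rows),
      outside = outside
    )
}
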