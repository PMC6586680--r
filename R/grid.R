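#' Georeferenced lattice specification
#'
#' A `grid_spec` describes a regular longitude/latitude lattice with square
#' cells: `n_rows` rows ordered north to south, `n_cols` columns ordered west
#' to east, an origin at the north-west corner (`x_min`, `y_max`) and a cell
#' size `resolution` in decimal degrees. Cell membership uses half-open
#' intervals `[edge, edge + resolution)` on both axes.
#'
#' The defaults mirror a Mesoamerican study window (longitudes -101..-77,
#' latitudes 7..22) at 2.5 arc-minute resolution, but any extent works; the
#' synthetic landscapes used in tests are much smaller.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_min Western edge, decimal degrees.
#' @param y_max Northern edge, decimal degrees.
#' @param resolution Cell size in decimal degrees (square cells).
#' @return An object of class `grid_spec` with fields `n_rows`, `n_cols`,
#'   `x_min`, `x_max`, `y_min`, `y_max`, `resolution`.
#' @examples
#' g <- grid_spec(10, 10, x_min = -101, y_max = 22, resolution = 0.5)
#' g$y_min
#' @export
grid_spec <- function(n_rows, n_cols, x_min = -101, y_max = 22,
                      resolution = 2.5 / 60) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be a positive number of degrees", call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         x_min = x_min, x_max = x_min + n_cols * resolution,
         y_min = y_max - n_rows * resolution, y_max = y_max,
         resolution = resolution),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols @ %.6g deg\n",
              x$n_rows, x$n_cols, x$resolution))
  cat(sprintf("  extent: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_min - b$x_min) < tol && abs(a$y_max - b$y_max) < tol &&
    abs(a$resolution - b$resolution) < tol
}

#' Map coordinates to grid cells and back
#'
#' `cell_of()` returns the (row, col) index of each coordinate pair under the
#' half-open cell convention, with `NA` for points outside the extent.
#' `cell_centre()` returns the lon/lat of cell centres.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @return `cell_of()`: a data.frame with integer columns `row`, `col`;
#'   `cell_centre()`: a data.frame with columns `lon`, `lat`.
#' @export
cell_of <- function(grid, lon, lat) {
  kx <- floor((lon - grid$x_min) / grid$resolution)
  ky <- floor((lat - grid$y_min) / grid$resolution)
  inside <- !is.na(kx) & !is.na(ky) &
    kx >= 0 & kx < grid$n_cols & ky >= 0 & ky < grid$n_rows
  row <- ifelse(inside, grid$n_rows - ky, NA_integer_)
  col <- ifelse(inside, kx + 1L, NA_integer_)
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' @rdname cell_of
#' @param row,col Integer vectors of cell indices (row 1 is northernmost).
#' @export
cell_centre <- function(grid, row, col) {
  data.frame(lon = grid$x_min + (col - 0.5) * grid$resolution,
             lat = grid$y_max - (row - 0.5) * grid$resolution)
}

#' Stack of co-registered predictor layers
#'
#' A `predictor_stack` bundles named raster layers (numeric matrices laid out
#' as the grid: row 1 = north) that share one [grid_spec()] and one validity
#' mask. Invalid cells (ocean / no data) are `NA` in every layer and `FALSE`
#' in the mask; no computation in the package reads them as data.
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices, each `n_rows x n_cols`.
#' @param mask Logical matrix of the same shape; `TRUE` marks valid cells.
#'   Defaults to all cells valid.
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(grid, layers, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(layers) == 0L) stop("at least one layer is required", call. = FALSE)
  nms <- names(layers)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("layers must have unique, non-empty names", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  if (!is.logical(mask) || !all(dim(mask) == c(grid$n_rows, grid$n_cols)))
    stop("mask must be a logical n_rows x n_cols matrix", call. = FALSE)
  layers <- lapply(layers, function(m) {
    if (!all(dim(m) == c(grid$n_rows, grid$n_cols)))
      stop("all layers must match the grid dimensions", call. = FALSE)
    m[!mask] <- NA_real_
    m
  })
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers on %d x %d grid (%d valid cells)\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

layer_names <- function(stack) names(stack$layers)

#' Extract predictor values at point locations
#'
#' Looks up the cell containing each coordinate pair and returns the layer
#' values there. Points outside the extent or on masked cells yield `NA` rows.
#'
#' @param stack A [predictor_stack()].
#' @param lon,lat Coordinate vectors (degrees).
#' @param layers Layer names to extract; default all.
#' @return A data.frame with one column per requested layer.
#' @export
extract_predictors <- function(stack, lon, lat, layers = NULL) {
  if (is.null(layers)) layers <- layer_names(stack)
  missing_l <- setdiff(layers, layer_names(stack))
  if (length(missing_l))
    stop("layer(s) not in stack: ", paste(missing_l, collapse = ", "),
         call. = FALSE)
  rc <- cell_of(stack$grid, lon, lat)
  idx <- ifelse(is.na(rc$row), NA_integer_,
                (rc$col - 1L) * stack$grid$n_rows + rc$row)
  out <- lapply(stack$layers[layers], function(m) m[idx])
  as.data.frame(out, optional = TRUE)
}

# data.frame of valid-cell values (cells x layers) with row/col bookkeeping
valid_cell_table <- function(stack, layers = NULL) {
  if (is.null(layers)) layers <- layer_names(stack)
  keep <- which(stack$mask)
  vals <- lapply(stack$layers[layers], function(m) m[keep])
  df <- as.data.frame(vals, optional = TRUE)
  attr(df, "cell_index") <- keep
  df
}
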