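#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange. `write_ascii_grid()` stores one matrix (laid
#' out north-to-south, as everywhere in this package) with the standard
#' six-line header; `read_ascii_grid()` returns the matrix together with the
#' reconstructed [grid_spec()]. `NA` cells are written as the nodata value.
#'
#' @param x Numeric or logical matrix (`n_rows x n_cols`).
#' @param grid The [grid_spec()] georeferencing `x`.
#' @param path File path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   a list with elements `values` (matrix) and `grid`.
#' @export
write_ascii_grid <- function(x, grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"),
            all(dim(x) == c(grid$n_rows, grid$n_cols)))
  x <- x * 1.0  # logical -> numeric
  x[is.na(x)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$x_min),
    sprintf("yllcorner %.10g", grid$y_min),
    sprintf("cellsize %.10g", grid$resolution),
    sprintf("NODATA_value %.10g", nodata)), con)
  utils::write.table(format(x, trim = TRUE, digits = 10, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA_real_
  g <- grid_spec(h[["nrows"]], h[["ncols"]], x_min = h[["xllcorner"]],
                 y_max = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]],
                 resolution = h[["cellsize"]])
  list(values = m, grid = g)
}

#' Read and write occurrence tables
#'
#' Occurrence CSVs carry the columns `species, lon, lat, year, source`
#' (missing years allowed). These helpers are thin wrappers that enforce the
#' column contract.
#'
#' @param records Data frame with at least `species`, `lon`, `lat`; `year`
#'   and `source` are added as `NA`/`"unknown"` when absent.
#' @param path File path.
#' @return `read_occurrences()` returns the validated data.frame.
#' @export
write_occurrences <- function(records, path) {
  records <- as_occurrence_table(records)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  as_occurrence_table(df)
}

as_occurrence_table <- function(df) {
  need <- c("species", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("occurrence table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$year)) df$year <- rep(NA_integer_, nrow(df))
  if (is.null(df$source)) df$source <- rep("unknown", nrow(df))
  df[c("species", "lon", "lat", "year", "source")]
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
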