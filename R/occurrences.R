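#' Occurrence set container
#'
#' Bundles a species' validated presence records with (optionally) its
#' pseudo-absences and a provenance log of every cleaning/thinning/sampling
#' step applied. Most users obtain one from [clean_occurrences()] and pass it
#' through [thin_systematic()] and [sample_pseudo_absences()].
#'
#' @param species Species identifier.
#' @param presences Occurrence data.frame (`species, lon, lat, year, source`).
#' @param pseudo_absences Data frame with `lon`, `lat`, or `NULL`.
#' @param grid The [grid_spec()] the records were validated against (used as
#'   the thinning anchor), or `NULL`.
#' @param provenance List of named log entries.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, presences,
                           pseudo_absences = NULL, grid = NULL,
                           provenance = list()) {
  presences <- as_occurrence_table(presences)
  structure(list(species = species, presences = presences,
                 pseudo_absences = pseudo_absences, grid = grid,
                 provenance = provenance),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set '%s': %d presences, %s pseudo-absences\n",
              x$species, nrow(x$presences),
              if (is.null(x$pseudo_absences)) "no"
              else nrow(x$pseudo_absences)))
  for (p in x$provenance)
    cat(sprintf("  [%s] %s\n", p$stage, p$note))
  invisible(x)
}

log_stage <- function(occ, stage, note) {
  occ$provenance <- c(occ$provenance, list(list(stage = stage, note = note)))
  occ
}

#' Clean raw occurrence records
#'
#' Applies the standard presence-validation rules for presence-only
#' biodiversity data, in order:
#' \enumerate{
#'   \item `incomplete_coordinates` — missing or non-finite lon/lat;
#'   \item `invalid_coordinates` — lon outside `[-180, 180]` or lat outside
#'     `[-90, 90]`;
#'   \item `outside_extent` — not on the study grid;
#'   \item `off_mask` — on an invalid (ocean / no-data) cell, the stand-in
#'     for implausible locations such as points in the sea;
#'   \item `before_min_year` — dated `min_year - 1` or earlier, so that
#'     records predating the baseline climate period are dropped. Records
#'     with a missing year are retained.
#' }
#' Each record is rejected under the first rule it violates; cleaning never
#' adds records, and rejection counts plus retained count equal the input
#' count.
#'
#' @param records Occurrence data.frame (see [read_occurrences()]).
#' @param stack The [predictor_stack()] whose grid and mask define validity.
#' @param min_year Earliest retained collection year (default 1960, matching
#'   a ~1960-1990 baseline climate).
#' @return An [occurrence_set()]; the rejection counts are in
#'   `$provenance` and in attribute `"rejections"` (named integer vector).
#' @examples
#' stk <- generate_predictor_stack(grid_spec(20, 20), seed = 1)
#' sp <- random_virtual_species(stk, seed = 2, name = "demo")
#' raw <- sample_occurrences(sp, stk, 50, seed = 3)
#' clean_occurrences(raw, stk)
#' @export
clean_occurrences <- function(records, stack, min_year = 1960L) {
  records <- as_occurrence_table(records)
  n_in <- nrow(records)
  reasons <- c("incomplete_coordinates", "invalid_coordinates",
               "outside_extent", "off_mask", "before_min_year")
  rej <- stats::setNames(integer(length(reasons)), reasons)

  bad <- !is.finite(records$lon) | !is.finite(records$lat)
  rej["incomplete_coordinates"] <- sum(bad)
  keep <- records[!bad, , drop = FALSE]

  bad <- abs(keep$lon) > 180 | abs(keep$lat) > 90
  rej["invalid_coordinates"] <- sum(bad)
  keep <- keep[!bad, , drop = FALSE]

  rc <- cell_of(stack$grid, keep$lon, keep$lat)
  bad <- is.na(rc$row)
  rej["outside_extent"] <- sum(bad)
  keep <- keep[!bad, , drop = FALSE]
  rc <- rc[!bad, , drop = FALSE]

  bad <- !stack$mask[cbind(rc$row, rc$col)]
  rej["off_mask"] <- sum(bad)
  keep <- keep[!bad, , drop = FALSE]

  bad <- !is.na(keep$year) & keep$year <= min_year - 1L
  rej["before_min_year"] <- sum(bad)
  keep <- keep[!bad, , drop = FALSE]

  sp <- unique(keep$species)
  if (length(sp) != 1L) sp <- unique(records$species)
  if (length(sp) != 1L) sp <- paste(sp, collapse = "+")
  occ <- occurrence_set(sp, keep, grid = stack$grid)
  occ <- log_stage(occ, "clean",
                   sprintf("%d in, %d retained; rejected: %s", n_in,
                           nrow(keep),
                           paste(names(rej), rej, sep = "=", collapse = ", ")))
  attr(occ, "rejections") <- rej
  occ
}

# (row, col) of the thinning cell for each record, grid anchored at
# (x_min, y_max) with half-open intervals; cell_size may differ from the
# stack resolution.
thinning_cell <- function(lon, lat, origin, cell_size) {
  kx <- floor((lon - origin[1]) / cell_size)
  ky <- floor((origin[2] - lat) / cell_size)
  # points exactly on the north edge belong to the first row
  ky[origin[2] - lat == 0] <- 0
  paste(ky, kx, sep = ":")
}

#' Systematic (grid) thinning of presence records
#'
#' Reduces sampling bias and spatial autocorrelation by overlaying a grid of
#' `cell_size` degrees (default 2.5 arc-min) anchored at the study-grid
#' origin and keeping exactly one presence per occupied cell, chosen
#' uniformly at random under `seed`. The output count therefore equals the
#' number of distinct occupied thinning cells, and re-thinning an already
#' thinned set is a no-op (idempotence).
#'
#' @param occ An [occurrence_set()] (its `grid`, when present, supplies the
#'   anchor) or an occurrence data.frame plus explicit `origin`.
#' @param cell_size Thinning cell size in degrees.
#' @param seed Integer seed for the per-cell uniform choice.
#' @param origin Anchor `c(x_min, y_max)`; defaults to the set's grid origin.
#' @return The [occurrence_set()] with thinned presences.
#' @export
thin_systematic <- function(occ, cell_size = 2.5 / 60, seed = 1L,
                            origin = NULL) {
  if (!inherits(occ, "occurrence_set"))
    occ <- occurrence_set(unique(as_occurrence_table(occ)$species)[1],
                          occ)
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (is.null(origin)) {
    if (is.null(occ$grid))
      stop("no grid on the occurrence set; supply `origin`", call. = FALSE)
    origin <- c(occ$grid$x_min, occ$grid$y_max)
  }
  pres <- occ$presences
  n_in <- nrow(pres)
  if (n_in > 0L) {
    key <- thinning_cell(pres$lon, pres$lat, origin, cell_size)
    pick <- with_seed(seed, {
      ord <- sample.int(n_in)  # random priority, then first per cell
      ord[!duplicated(key[ord])]
    })
    pres <- pres[sort(pick), , drop = FALSE]
    rownames(pres) <- NULL
  }
  occ$presences <- pres
  log_stage(occ, "thin",
            sprintf("%d in, %d retained (one per %.6g-deg cell)",
                    n_in, nrow(pres), cell_size))
}

#' Sample pseudo-absence locations
#'
#' Draws `n` distinct cells uniformly without replacement from the valid
#' cells of the study area — minus the cells holding presences when
#' `exclude_presence_cells` is set (the default, preventing label
#' contamination) — and places one pseudo-absence at each cell centre.
#' "Without replacement" operates at cell level: one pseudo-absence per cell.
#'
#' @param occ An [occurrence_set()].
#' @param stack The [predictor_stack()] defining valid cells.
#' @param n Number of pseudo-absences (default 1000).
#' @param exclude_presence_cells Exclude cells containing presences?
#' @param seed Integer seed.
#' @return The [occurrence_set()] with `$pseudo_absences` filled
#'   (`lon`, `lat` at cell centres).
#' @export
sample_pseudo_absences <- function(occ, stack, n = 1000L,
                                   exclude_presence_cells = TRUE,
                                   seed = 1L) {
  stopifnot(inherits(occ, "occurrence_set"), n >= 1L)
  eligible <- which(stack$mask)
  if (exclude_presence_cells && nrow(occ$presences) > 0L) {
    rc <- cell_of(stack$grid, occ$presences$lon, occ$presences$lat)
    pres_idx <- (rc$col - 1L) * stack$grid$n_rows + rc$row
    eligible <- setdiff(eligible, pres_idx[!is.na(pres_idx)])
  }
  if (length(eligible) < n)
    stop(sprintf(
      "cannot sample %d pseudo-absences from %d eligible cells",
      n, length(eligible)), call. = FALSE)
  cells <- with_seed(seed, eligible[sample.int(length(eligible), n)])
  row <- ((cells - 1L) %% stack$grid$n_rows) + 1L
  col <- ((cells - 1L) %/% stack$grid$n_rows) + 1L
  occ$pseudo_absences <- cell_centre(stack$grid, row, col)
  log_stage(occ, "pseudo_absences",
            sprintf("%d cells sampled without replacement from %d eligible",
                    n, length(eligible)))
}

# presence/pseudo-absence predictor table for model fitting
training_table <- function(occ, stack, layers) {
  if (is.null(occ$pseudo_absences))
    stop("occurrence set has no pseudo-absences yet", call. = FALSE)
  xp <- extract_predictors(stack, occ$presences$lon, occ$presences$lat,
                           layers)
  xa <- extract_predictors(stack, occ$pseudo_absences$lon,
                           occ$pseudo_absences$lat, layers)
  x <- rbind(xp, xa)
  y <- c(rep(1L, nrow(xp)), rep(0L, nrow(xa)))
  ok <- stats::complete.cases(x)
  list(x = x[ok, , drop = FALSE], y = y[ok])
}
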