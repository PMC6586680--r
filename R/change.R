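#' Change-category codes
#'
#' Integer codes used in change maps: 0 `never` (absent in both periods),
#' 1 `remain` (present in both), 2 `loss` (present only at baseline,
#' "vulnerable"), 3 `gain` (present only in the future).
#' @return Named integer vector.
#' @export
change_codes <- function() {
  c(never = 0L, remain = 1L, loss = 2L, gain = 3L)
}

#' Classify suitability change between baseline and future
#'
#' Cross-tabulates two binary presence maps into the four mutually exclusive
#' change categories. By construction `remain + loss` partitions the
#' baseline presence and `remain + gain` partitions the future presence.
#'
#' @param baseline,future Logical presence matrices on one grid.
#' @param grid Optional [grid_spec()] attached for area weighting.
#' @return An object of class `change_map`: integer matrix of
#'   [change_codes()] with attributes `grid`, `baseline` and `future`.
#' @export
classify_change <- function(baseline, future, grid = NULL) {
  if (!all(dim(baseline) == dim(future)))
    stop("baseline and future maps have mismatched grids", call. = FALSE)
  cc <- change_codes()
  ok <- !is.na(baseline) & !is.na(future)
  out <- matrix(NA_integer_, nrow(baseline), ncol(baseline))
  out[ok & !baseline & !future] <- cc[["never"]]
  out[ok & baseline & future] <- cc[["remain"]]
  out[ok & baseline & !future] <- cc[["loss"]]
  out[ok & !baseline & future] <- cc[["gain"]]
  structure(out, class = "change_map", grid = grid,
            baseline = baseline, future = future)
}

# logical mask of one change category; NA (masked) cells map to FALSE
category_mask <- function(change, category) {
  m <- unclass(change) == change_codes()[[category]]
  m[is.na(m)] <- FALSE
  m
}

# cell areas: unit cells, or km2 with cos(latitude) correction
cell_area_weights <- function(change, area_mode) {
  if (area_mode == "cells") return(matrix(1, nrow(change), ncol(change)))
  grid <- attr(change, "grid")
  if (is.null(grid))
    stop("cos_lat_km2 area mode needs a change map built with a grid",
         call. = FALSE)
  lat <- cell_centre(grid, seq_len(grid$n_rows), 1L)$lat
  km_per_deg <- 111.32
  w <- (grid$resolution * km_per_deg)^2 * cos(lat * pi / 180)
  matrix(w, grid$n_rows, grid$n_cols)
}

#' Area change relative to baseline
#'
#' Loss, gain and remain areas expressed as percentages of the baseline
#' presence area, the convention of range-shift studies ("x% of current
#' areas will no longer be suitable"). `loss + remain = 100` by the
#' partition identity; gain can exceed 100 for expanding ranges.
#'
#' @param change A [classify_change()] map with non-empty baseline presence.
#' @param area_mode `"cells"` (count cells) or `"cos_lat_km2"`
#'   (cos-latitude-weighted km^2; requires a grid).
#' @return Named numeric vector `c(loss, gain, remain)` in percent.
#' @export
area_change_percent <- function(change, area_mode = c("cells",
                                                      "cos_lat_km2")) {
  area_mode <- match.arg(area_mode)
  w <- cell_area_weights(change, area_mode)
  a <- function(cat) sum(w[which(category_mask(change, cat))])
  base <- a("remain") + a("loss")
  if (base <= 0) stop("baseline presence is empty", call. = FALSE)
  c(loss = 100 * a("loss") / base,
    gain = 100 * a("gain") / base,
    remain = 100 * a("remain") / base)
}

#' Named altitude bands
#'
#' Default reporting bands: lowland `[0, 300)` m, mid-altitude `[400, 700)`
#' m and highland `[1800, Inf)` m above sea level. The gap between 300 and
#' 400 m is intentional — band edges are configurable and nothing is assumed
#' about it.
#' @return Named list of `c(lo, hi)` pairs (half-open intervals).
#' @export
default_altitude_bands <- function() {
  list(lowland = c(0, 300), mid_altitude = c(400, 700),
       highland = c(1800, Inf))
}

#' Altitudinal profile of suitability change
#'
#' Counts change-category cells in uniform elevation bins of `bin_width`
#' metres (half-open `[lo, lo + width)`), plus the named aggregate bands of
#' `default_altitude_bands()`.
#'
#' @param change A [classify_change()] map.
#' @param elevation Elevation matrix (m a.s.l.) on the same grid.
#' @param bin_width Uniform bin width in metres (default 100).
#' @param bands Named list of aggregate bands.
#' @return An object of class `altitudinal_profile`: list with `bins`
#'   (data.frame: lower edge + one count column per category) and `bands`
#'   (same layout for the named bands).
#' @export
altitudinal_profile <- function(change, elevation, bin_width = 100,
                                bands = default_altitude_bands()) {
  if (!all(dim(change) == dim(elevation)))
    stop("elevation raster has a mismatched grid", call. = FALSE)
  ok <- !is.na(unclass(change)) & !is.na(elevation)
  elev <- elevation[ok]
  cat_ <- unclass(change)[ok]
  lo <- floor(min(elev) / bin_width) * bin_width
  edges <- seq(lo, max(elev) + bin_width, by = bin_width)
  bin <- findInterval(elev, edges, rightmost.closed = FALSE)
  cc <- change_codes()
  count_in <- function(sel) {
    vapply(cc, function(code) sum(cat_[sel] == code), integer(1))
  }
  bins <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(b) {
    data.frame(elevation_lo = edges[b], t(count_in(bin == b)))
  }))
  band_tab <- do.call(rbind, lapply(names(bands), function(nm) {
    r <- bands[[nm]]
    data.frame(band = nm, lo = r[1], hi = r[2],
               t(count_in(elev >= r[1] & elev < r[2])))
  }))
  structure(list(bins = bins, bands = band_tab, bin_width = bin_width),
            class = "altitudinal_profile")
}

#' Crop replacement analysis
#'
#' Where crop A loses suitability, can crop B take over? Categories:
#' \describe{
#'   \item{replaceable}{A-loss cells inside B's future range}
#'   \item{no_alternative}{A-loss cells outside B's future range}
#'   \item{both_suitable}{cells in both crops' future ranges}
#'   \item{crop_a_only}{A-future cells outside B's future range}
#' }
#' `replaceable` and `no_alternative` partition A's loss exactly. When an
#' elevation raster is supplied, the replaceable fraction of A's loss is
#' also reported per altitude band.
#'
#' @param change_a [classify_change()] map of crop A.
#' @param future_b Logical future presence map of crop B (same grid).
#' @param elevation Optional elevation matrix for per-band fractions.
#' @param bands Named altitude bands (default [default_altitude_bands()]).
#' @return An object of class `replacement_map`: integer category matrix
#'   (codes in `$codes`), overall `replaceable_fraction` of A-loss, and
#'   `band_fractions` (data.frame or `NULL`).
#' @export
replacement_analysis <- function(change_a, future_b, elevation = NULL,
                                 bands = default_altitude_bands()) {
  if (!all(dim(change_a) == dim(future_b)))
    stop("crop maps have mismatched grids", call. = FALSE)
  loss_a <- category_mask(change_a, "loss")
  future_a <- attr(change_a, "future")
  future_a[is.na(future_a)] <- FALSE
  fb <- future_b
  fb[is.na(fb)] <- FALSE
  codes <- c(other = 0L, replaceable = 1L, both_suitable = 2L,
             no_alternative = 3L, crop_a_only = 4L)
  out <- matrix(NA_integer_, nrow(future_b), ncol(future_b))
  out[!is.na(unclass(change_a))] <- codes[["other"]]
  out[loss_a & fb] <- codes[["replaceable"]]
  out[loss_a & !fb & !is.na(unclass(change_a))] <- codes[["no_alternative"]]
  out[future_a & fb] <- codes[["both_suitable"]]
  out[future_a & !fb] <- codes[["crop_a_only"]]
  n_loss <- sum(loss_a)
  frac <- if (n_loss > 0) sum(loss_a & fb) / n_loss else NA_real_
  band_fractions <- NULL
  if (!is.null(elevation)) {
    band_fractions <- do.call(rbind, lapply(names(bands), function(nm) {
      r <- bands[[nm]]
      in_band <- !is.na(elevation) & elevation >= r[1] & elevation < r[2]
      nl <- sum(loss_a & in_band)
      data.frame(band = nm, loss_cells = nl,
                 replaceable_fraction =
                   if (nl > 0) sum(loss_a & fb & in_band) / nl
                   else NA_real_)
    }))
  }
  structure(list(map = out, codes = codes,
                 replaceable_fraction = frac,
                 band_fractions = band_fractions),
            class = "replacement_map")
}

#' Tree-portfolio richness in crop areas
#'
#' For every cell of a crop's area of interest, counts how many candidate
#' agroforestry tree species are projected suitable, in total and per use
#' group (fruit, N-fixing, timber), then classifies cells:
#' `high_option` when total richness exceeds `rich_total` AND every group
#' offers at least `rich_per_group` species; `low_option` when total
#' richness is at most `low_cutoff`; `other` otherwise.
#'
#' @param per_species_future Named list of logical future presence maps,
#'   one per tree species, all on one grid.
#' @param groups Named character vector mapping every species to exactly one
#'   use group.
#' @param crop_area Logical matrix of the crop cells to evaluate (e.g.
#'   baseline-or-future crop presence).
#' @param rich_total Total-richness bound for `high_option` (strict `>`,
#'   default 30).
#' @param rich_per_group Per-group minimum for `high_option` (default 10).
#' @param low_cutoff Total-richness ceiling for `low_option` (default 3).
#' @return An object of class `portfolio_map`: `total` and per-group
#'   richness matrices, the cell `classes` matrix (codes in `$codes`), and
#'   `fractions` (share of crop-area cells per class).
#' @export
portfolio_richness <- function(per_species_future, groups, crop_area,
                               rich_total = 30L, rich_per_group = 10L,
                               low_cutoff = 3L) {
  sp <- names(per_species_future)
  miss <- setdiff(sp, names(groups))
  if (length(miss))
    stop("species without group assignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- dim(crop_area)
  for (m in per_species_future)
    if (!all(dim(m) == d)) stop("mismatched grids", call. = FALSE)
  zero <- matrix(0L, d[1], d[2])
  total <- zero
  by_group <- list()
  for (s in sp) {
    pres <- per_species_future[[s]] & !is.na(per_species_future[[s]])
    pres[is.na(per_species_future[[s]])] <- FALSE
    total <- total + pres
    g <- groups[[s]]
    if (is.null(by_group[[g]])) by_group[[g]] <- zero
    by_group[[g]] <- by_group[[g]] + pres
  }
  codes <- c(other = 0L, high_option = 1L, low_option = 2L)
  in_crop <- crop_area & !is.na(crop_area)
  in_crop[is.na(crop_area)] <- FALSE
  group_ok <- Reduce(`&`, lapply(by_group, function(m) m >= rich_per_group))
  classes <- matrix(NA_integer_, d[1], d[2])
  classes[in_crop] <- codes[["other"]]
  classes[in_crop & total > rich_total & group_ok] <- codes[["high_option"]]
  classes[in_crop & total <= low_cutoff] <- codes[["low_option"]]
  n_crop <- sum(in_crop)
  fractions <- vapply(names(codes), function(nm)
    if (n_crop > 0) sum(classes[in_crop] == codes[[nm]]) / n_crop
    else NA_real_, numeric(1))
  structure(list(total = total, by_group = by_group, classes = classes,
                 codes = codes, fractions = fractions, n_crop = n_crop),
            class = "portfolio_map")
}

#' Per-species suitable-area change table
#'
#' Summarises each species' baseline and future suitable area and the
#' percentage change `100 * (future - baseline) / baseline`, ordered by use
#' group and change magnitude, with counts of species losing or gaining
#' more than `big_change` percent per group (the winners-and-losers view).
#' Species with an empty baseline get `NA` change and are excluded from the
#' counts (and listed in attribute `"undefined"`).
#'
#' @param per_species_change Named list of [classify_change()] maps.
#' @param groups Named character vector: species to use group.
#' @param big_change Absolute percent-change threshold for the per-group
#'   counts (default 15).
#' @return Data frame `species, group, baseline_cells, future_cells,
#'   pct_change`, sorted by group then decreasing `|pct_change|`, with
#'   attribute `"big_change_counts"` (data.frame per group: `n_loss_gt`,
#'   `n_gain_gt`).
#' @export
species_area_change_table <- function(per_species_change, groups,
                                      big_change = 15) {
  stopifnot(length(per_species_change) >= 1L)
  sp <- names(per_species_change)
  rows <- lapply(sp, function(s) {
    ch <- per_species_change[[s]]
    base <- sum(category_mask(ch, "remain") | category_mask(ch, "loss"),
                na.rm = TRUE)
    fut <- sum(category_mask(ch, "remain") | category_mask(ch, "gain"),
               na.rm = TRUE)
    data.frame(species = s,
               group = if (s %in% names(groups)) groups[[s]]
                       else NA_character_,
               baseline_cells = base, future_cells = fut,
               pct_change = if (base > 0) 100 * (fut - base) / base
                            else NA_real_)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$group, -abs(tab$pct_change)), , drop = FALSE]
  rownames(tab) <- NULL
  defined <- tab[!is.na(tab$pct_change), , drop = FALSE]
  counts <- do.call(rbind, lapply(split(defined, defined$group), function(d) {
    data.frame(group = d$group[1],
               n_loss_gt = sum(d$pct_change < -big_change),
               n_gain_gt = sum(d$pct_change > big_change))
  }))
  rownames(counts) <- NULL
  attr(tab, "big_change_counts") <- counts
  attr(tab, "undefined") <- tab$species[is.na(tab$pct_change)]
  tab
}
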