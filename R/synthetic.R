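#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# Every stochastic operation in the package funnels through this, so results
# are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env))
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed for a named stage, kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(seed) %% 65521) * 32749 + h) %% 2147483629L + 1L
}

# Moving-average smoother (separable box filter) with edge replication.
# Fixed-window smoothing of white noise gives the spatial autocorrelation of
# the synthetic climate surfaces.
smooth2d <- function(m, window = 5L) {
  if (window <= 1L) return(m)
  pad <- window  # generous edge padding, cropped after filtering
  nr <- nrow(m); nc <- ncol(m)
  mp <- m[c(rep(1L, pad), seq_len(nr), rep(nr, pad)),
          c(rep(1L, pad), seq_len(nc), rep(nc, pad)), drop = FALSE]
  w <- rep(1 / window, window)
  mp <- apply(mp, 2L, function(v) stats::filter(v, w, sides = 2L))
  mp <- t(apply(mp, 1L, function(v) stats::filter(v, w, sides = 2L)))
  mp[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
}

# Bioclim convention: variables 1-11 are temperature-derived, 12-19
# precipitation-derived. Non-bioXX names default to temperature-like.
is_temperature_layer <- function(nm) {
  num <- suppressWarnings(as.integer(sub("^bio0?", "", nm)))
  ifelse(grepl("^bio[0-9]+$", nm), !is.na(num) & num <= 11L, TRUE)
}

#' Default bioclimatic layer names
#'
#' The nine low-collinearity bioclim variables used throughout the examples:
#' mean diurnal range (bio02), isothermality (bio03), mean temperature of the
#' wettest and driest quarters (bio08, bio09), precipitation of the wettest
#' and driest months (bio13, bio14), precipitation seasonality (bio15) and
#' precipitation of the warmest and coldest quarters (bio18, bio19).
#' @return Character vector of nine layer names.
#' @export
default_bioclim_layers <- function() {
  c("bio02", "bio03", "bio08", "bio09", "bio13",
    "bio14", "bio15", "bio18", "bio19")
}

#' Generate a synthetic bioclimatic predictor stack
#'
#' Builds a WorldClim-like raster stack on `grid`: each layer is a
#' deterministic large-scale gradient plus a spatially autocorrelated random
#' field (moving-average smoothed white noise). An `elevation` layer is always
#' produced; the lowest `ocean_fraction` of its cells become the invalid
#' (ocean) mask shared by all layers, with elevation zeroed at the coastline.
#' With `elevation_coupling` (the default), temperature-like layers decrease
#' with elevation at a standard environmental lapse rate of 6.5 degC per km,
#' so warming scenarios push suitability upslope, as on a real mountain
#' landscape. Identical `(grid, layer_names, seed, ...)` give bit-identical
#' output.
#'
#' Temperature-like layers (bioclim 1-11) are drawn on a degree-Celsius-like
#' scale (landscape mean around 24, gradients of a few degrees);
#' precipitation-like layers (bioclim 12-19) on a millimetre-like scale,
#' truncated at zero.
#'
#' @param grid A [grid_spec()].
#' @param layers Character vector of layer names (default the nine
#'   bioclim predictors of [default_bioclim_layers()]).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param elevation_coupling Couple temperature-like layers to elevation?
#' @param ocean_fraction Fraction of cells masked as ocean (lowest elevation).
#' @param smooth_window Box-filter window (cells) for the random fields.
#' @return A [predictor_stack()] containing `layers` plus `"elevation"`.
#' @examples
#' stk <- generate_predictor_stack(grid_spec(30, 30), seed = 1)
#' names(stk$layers)
#' @export
generate_predictor_stack <- function(grid,
                                     layers = default_bioclim_layers(),
                                     seed = 1L,
                                     elevation_coupling = TRUE,
                                     ocean_fraction = 0.1,
                                     smooth_window = 5L) {
  if (length(layers) == 0L) stop("layers must be non-empty", call. = FALSE)
  if ("elevation" %in% layers)
    stop("'elevation' is generated automatically; do not list it", call. = FALSE)
  nr <- grid$n_rows; nc <- grid$n_cols
  rowf <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc)
  colf <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  with_seed(seed, {
    # elevation first: its mask applies to everything
    a <- stats::runif(1, -1, 1); b <- stats::runif(1, -1, 1)
    noise <- smooth2d(matrix(stats::rnorm(nr * nc), nr, nc), smooth_window)
    elev <- 1200 * (a * rowf + b * colf) + 900 * noise / stats::sd(noise)
    sea_level <- stats::quantile(elev, ocean_fraction, names = FALSE)
    elev <- elev - sea_level
    mask <- elev >= 0
    out <- list()
    for (nm in layers) {
      a <- stats::runif(1, -1, 1); b <- stats::runif(1, -1, 1)
      noise <- smooth2d(matrix(stats::rnorm(nr * nc), nr, nc), smooth_window)
      noise <- noise / stats::sd(noise)
      if (is_temperature_layer(nm)) {
        lyr <- 24 + 6 * (a * rowf + b * colf) + 1.5 * noise
        if (elevation_coupling) lyr <- lyr - 0.0065 * pmax(elev, 0)
      } else {
        lyr <- 150 + 100 * (a * rowf + b * colf) + 40 * noise
        lyr <- pmax(lyr, 0)
      }
      out[[nm]] <- lyr
    }
    out[["elevation"]] <- elev
    predictor_stack(grid, out, mask)
  })
}

#' Virtual species with a known climatic niche
#'
#' A virtual species defines ground-truth habitat suitability as a product of
#' independent Gaussian responses over a subset of predictor layers:
#' `s(x) = prod_j exp(-0.5 * ((v_j(x) - mu_j) / sigma_j)^2)`, the standard
#' virtual-species construction. Suitability is 1 at the niche centre and
#' decays towards 0 away from it.
#'
#' @param name Species identifier.
#' @param niche Data frame with columns `layer`, `mu`, `sigma` (one row per
#'   predictor the species responds to); all `sigma > 0`.
#' @param prevalence_target Nominal fraction of the landscape intended to be
#'   suitable; stored as metadata (used by [random_virtual_species()] to set
#'   niche breadths).
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(name, niche, prevalence_target = 0.1) {
  niche <- as.data.frame(niche)
  stopifnot(all(c("layer", "mu", "sigma") %in% names(niche)))
  if (any(!is.finite(niche$sigma)) || any(niche$sigma <= 0))
    stop("all niche widths (sigma) must be positive", call. = FALSE)
  if (anyDuplicated(niche$layer))
    stop("duplicate layer in niche definition", call. = FALSE)
  if (!is.finite(prevalence_target) || prevalence_target <= 0 ||
      prevalence_target > 1)
    stop("prevalence_target must be in (0, 1]", call. = FALSE)
  structure(list(name = name, niche = niche,
                 prevalence_target = prevalence_target),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("virtual_species '%s' over %d layer(s): %s\n", x$name,
              nrow(x$niche), paste(x$niche$layer, collapse = ", ")))
  invisible(x)
}

#' Draw a random virtual species on a landscape
#'
#' Centres the niche on the predictor values of a randomly chosen valid cell,
#' sets the relative width of each response to `breadth` times the landscape
#' standard deviation of that layer, and then rescales all widths by a common
#' factor so that the species' continuous prevalence — the landscape mean of
#' true suitability — equals `prevalence_target`. Without this calibration a
#' niche centred on a rare predictor combination can occupy a vanishing
#' fraction of the landscape, which is not a realistic modelling target.
#' Because `s = exp(-0.5 * sum(z^2))`, scaling every `sigma` by `c` maps `s`
#' to `s^(1/c^2)`, so the calibration reduces to a monotone one-dimensional
#' root find.
#'
#' @param stack A [predictor_stack()].
#' @param layers Layers the niche responds to (default: all except elevation).
#' @param seed Integer seed.
#' @param breadth Relative niche width (multiple of layer standard
#'   deviation) before prevalence calibration.
#' @param name Species name.
#' @inheritParams virtual_species
#' @return A [virtual_species()] whose mean suitability over valid cells is
#'   `prevalence_target` (to root-find tolerance).
#' @export
random_virtual_species <- function(stack, layers = NULL, seed = 1L,
                                   breadth = 0.6, name = "virtual",
                                   prevalence_target = 0.1) {
  if (is.null(layers)) layers <- setdiff(layer_names(stack), "elevation")
  vals <- valid_cell_table(stack, layers)
  with_seed(seed, {
    centre <- vals[sample.int(nrow(vals), 1L), , drop = FALSE]
    niche <- data.frame(
      layer = layers,
      mu = as.numeric(centre[1L, ]),
      sigma = vapply(vals, stats::sd, numeric(1)) * breadth)
    sp <- virtual_species(name, niche, prevalence_target)
    s <- true_suitability(sp, stack)[stack$mask]
    # scale all sigma by c: s -> s^(1/c^2); solve mean(s^a) = target in a
    f <- function(log_a) mean(s^exp(log_a)) - prevalence_target
    if (f(log(1e-6)) > 0 && f(log(1e6)) < 0) {
      a <- exp(stats::uniroot(f, c(log(1e-6), log(1e6)), tol = 1e-10)$root)
      sp$niche$sigma <- sp$niche$sigma / sqrt(a)
    }
    sp
  })
}

#' Ground-truth suitability surface of a virtual species
#'
#' @param species A [virtual_species()].
#' @param stack A [predictor_stack()] providing every niche layer.
#' @return Numeric matrix in `[0, 1]`; masked cells stay `NA`.
#' @export
true_suitability <- function(species, stack) {
  stopifnot(inherits(species, "virtual_species"))
  miss <- setdiff(species$niche$layer, layer_names(stack))
  if (length(miss))
    stop("niche layer(s) missing from stack: ", paste(miss, collapse = ", "),
         call. = FALSE)
  s <- matrix(1, stack$grid$n_rows, stack$grid$n_cols)
  for (i in seq_len(nrow(species$niche))) {
    v <- stack$layers[[species$niche$layer[i]]]
    z <- (v - species$niche$mu[i]) / species$niche$sigma[i]
    s <- s * exp(-0.5 * z^2)
  }
  s[!stack$mask] <- NA_real_
  s
}

#' Sample presence-only occurrence records from a virtual species
#'
#' Draws `n` presence records (with replacement across cells) with per-cell
#' probability proportional to true suitability times an optional sampling
#' bias surface, emulating opportunistically collected presence-only data.
#' Records are reported at cell centres; collection years are drawn uniformly
#' from `year_range`.
#'
#' @param species A [virtual_species()].
#' @param stack A [predictor_stack()].
#' @param n Number of records (>= 1).
#' @param bias Optional non-negative weight matrix (sampling effort).
#' @param seed Integer seed.
#' @param year_range Inclusive range collection years are drawn from.
#' @param source Value for the `source` column.
#' @return Occurrence data.frame (`species, lon, lat, year, source`).
#' @export
sample_occurrences <- function(species, stack, n, bias = NULL, seed = 1L,
                               year_range = c(1970L, 2015L),
                               source = "virtual") {
  stopifnot(n >= 1)
  s <- true_suitability(species, stack)
  w <- s
  if (!is.null(bias)) {
    stopifnot(all(dim(bias) == dim(s)))
    w <- w * bias
  }
  idx <- which(stack$mask & !is.na(w) & w > 0)
  if (length(idx) == 0L || sum(w[idx]) <= 0)
    stop("all sampling weights are zero", call. = FALSE)
  with_seed(seed, {
    cells <- idx[sample.int(length(idx), n, replace = TRUE, prob = w[idx])]
    yrs <- sample(seq.int(year_range[1], year_range[2]), n, replace = TRUE)
    rc_row <- ((cells - 1L) %% stack$grid$n_rows) + 1L
    rc_col <- ((cells - 1L) %/% stack$grid$n_rows) + 1L
    ctr <- cell_centre(stack$grid, rc_row, rc_col)
    data.frame(species = species$name, lon = ctr$lon, lat = ctr$lat,
               year = yrs, source = source)
  })
}

#' Pseudo-GCM climate-change scenario
#'
#' A scenario is an additive per-layer mean shift (e.g. +1.4 degC on
#' temperature-like layers for an intermediate-emissions pathway, +2.0 degC
#' for a high-emissions one) realised by `gcm_count` pseudo-GCMs. Each GCM g
#' applies `mean_shift + eps_g`, where `eps_g` is a per-GCM, per-layer
#' spatially constant deviation with standard deviation `gcm_spread` — GCMs
#' are alternative plausible futures, not spatial error fields.
#'
#' @param name Scenario identifier (e.g. `"rcp45-like"`).
#' @param mean_shift Named numeric vector: additive delta per layer.
#' @param gcm_count Number of pseudo-GCMs (default 17).
#' @param gcm_spread Standard deviation of per-GCM deviations; scalar or
#'   named vector aligned with `mean_shift`.
#' @param seed Integer seed for the GCM deviations.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, mean_shift, gcm_count = 17L, gcm_spread = 0,
                          seed = 1L) {
  stopifnot(length(mean_shift) >= 1L, !is.null(names(mean_shift)))
  gcm_count <- as.integer(gcm_count)
  if (is.na(gcm_count) || gcm_count < 1L)
    stop("gcm_count must be >= 1", call. = FALSE)
  if (length(gcm_spread) == 1L && is.null(names(gcm_spread)))
    gcm_spread <- stats::setNames(rep(gcm_spread, length(mean_shift)),
                                  names(mean_shift))
  gcm_spread <- gcm_spread[names(mean_shift)]
  if (any(is.na(gcm_spread)) || any(gcm_spread < 0))
    stop("gcm_spread must be non-negative for every shifted layer",
         call. = FALSE)
  structure(list(name = name, mean_shift = mean_shift,
                 gcm_count = gcm_count, gcm_spread = gcm_spread,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate per-GCM future predictor stacks
#'
#' @param baseline Baseline [predictor_stack()].
#' @param scenario A [scenario_spec()]; every `mean_shift` name must be a
#'   baseline layer.
#' @return A named list (`gcm01`, `gcm02`, ...) of `gcm_count` stacks. The
#'   matrix of per-GCM applied deltas is attached as attribute
#'   `"applied_deltas"` (GCM x layer).
#' @export
generate_future_stacks <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "predictor_stack"),
            inherits(scenario, "scenario_spec"))
  unknown <- setdiff(names(scenario$mean_shift), layer_names(baseline))
  if (length(unknown))
    stop("mean_shift names not in baseline stack: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  g <- scenario$gcm_count
  lyr <- names(scenario$mean_shift)
  deltas <- with_seed(scenario$seed, {
    eps <- matrix(stats::rnorm(g * length(lyr)), g, length(lyr))
    sweep(eps, 2L, scenario$gcm_spread, `*`) +
      matrix(scenario$mean_shift, g, length(lyr), byrow = TRUE)
  })
  dimnames(deltas) <- list(sprintf("gcm%02d", seq_len(g)), lyr)
  out <- lapply(seq_len(g), function(i) {
    layers <- baseline$layers
    for (nm in lyr) layers[[nm]] <- layers[[nm]] + deltas[i, nm]
    predictor_stack(baseline$grid, layers, baseline$mask)
  })
  names(out) <- rownames(deltas)
  attr(out, "applied_deltas") <- deltas
  out
}
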