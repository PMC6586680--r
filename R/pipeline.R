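#' Default pseudo-scenarios
#'
#' Two additive climate-change scenarios patterned on mid-century projections
#' for an intermediate and a high emissions pathway: temperature-like layers
#' shift by +1.4 degC (`rcp45-like`) or +2.0 degC (`rcp85-like`) with a
#' per-GCM spread of 0.3 degC (matching the roughly +/-0.55 degC range
#' across models), and precipitation-like layers dry by 10 mm with a 10 mm
#' per-GCM spread.
#'
#' @param gcm_count Pseudo-GCMs per scenario (default 17).
#' @return List of two scenario parameter lists consumable by
#'   [pipeline_config()].
#' @export
default_scenarios <- function(gcm_count = 17L) {
  list(
    list(name = "rcp45-like", temp_shift = 1.4, precip_shift = -10,
         temp_spread = 0.3, precip_spread = 10, gcm_count = gcm_count),
    list(name = "rcp85-like", temp_shift = 2.0, precip_shift = -10,
         temp_spread = 0.3, precip_spread = 10, gcm_count = gcm_count))
}

# scenario parameter list -> scenario_spec over the given layers
build_scenario <- function(sc, layers, seed) {
  temp <- layers[is_temperature_layer(layers)]
  prec <- setdiff(layers, temp)
  shift <- c(stats::setNames(rep(sc$temp_shift, length(temp)), temp),
             stats::setNames(rep(sc$precip_shift %||% 0, length(prec)), prec))
  spread <- c(stats::setNames(rep(sc$temp_spread %||% 0, length(temp)), temp),
              stats::setNames(rep(sc$precip_spread %||% 0, length(prec)),
                              prec))
  scenario_spec(sc$name, shift, gcm_count = sc$gcm_count %||% 17L,
                gcm_spread = spread, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Validated parameter bundle for [run_pipeline()]. All defaults follow the
#' method conventions used throughout the package: 2.5 arc-min cells, 1000
#' pseudo-absences, 4-fold cross-validation, AUC weight cutoff 0.05, VIF
#' threshold 10 and 66% GCM agreement. `seed` is mandatory — every
#' stochastic stage derives a child seed from it by stable hashing, so a
#' rerun with the same config is bit-reproducible.
#'
#' @param seed Integer seed (mandatory).
#' @param grid Grid parameters: list with `n_rows`, `n_cols`, and optionally
#'   `x_min`, `y_max`, `resolution`.
#' @param layers Predictor layer names to simulate.
#' @param species Data frame with columns `name`, `group` (`"crop"` or a
#'   tree use group such as `"fruit"`, `"n_fixing"`, `"timber"`); the first
#'   two crops are used for the replacement analysis.
#' @param n_occurrences Presence records sampled per species.
#' @param n_pseudo_absences Pseudo-absences per species (default 1000).
#' @param min_year Cleaning year cutoff (default 1960).
#' @param thin_cell Thinning cell size in degrees (default: grid
#'   resolution, i.e. 2.5 arc-min at the default grid).
#' @param k Cross-validation folds (default 4).
#' @param weight_cutoff AUC raw-weight cutoff (default 0.05).
#' @param vif_threshold VIF removal threshold (default 10).
#' @param agreement GCM agreement fraction, in (0.5, 1] (default 0.66).
#' @param learners Names of built-in learners to use (see
#'   [default_learners()]).
#' @param scenarios List of scenario parameter lists (see
#'   [default_scenarios()]).
#' @param portfolio List with `rich_total`, `rich_per_group`, `low_cutoff`
#'   thresholds for [portfolio_richness()].
#' @param occurrences_csv Optional path to a raw occurrence CSV; when given,
#'   records are read from it instead of being sampled from the virtual
#'   species.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            grid = list(n_rows = 50L, n_cols = 50L),
                            layers = default_bioclim_layers(),
                            species = data.frame(
                              name = c("coffea_like", "theobroma_like",
                                       "inga_like"),
                              group = c("crop", "crop", "n_fixing")),
                            n_occurrences = 300L,
                            n_pseudo_absences = 1000L,
                            min_year = 1960L,
                            thin_cell = NULL,
                            k = 4L,
                            weight_cutoff = 0.05,
                            vif_threshold = 10,
                            agreement = 0.66,
                            learners = names(default_learners()),
                            scenarios = default_scenarios(gcm_count = 5L),
                            portfolio = list(rich_total = 30L,
                                             rich_per_group = 10L,
                                             low_cutoff = 3L),
                            occurrences_csv = NULL) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("seed is mandatory", call. = FALSE)
  if (agreement <= 0.5 || agreement > 1)
    stop("agreement must lie in (0.5, 1]", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (weight_cutoff < 0 || weight_cutoff >= 1)
    stop("weight_cutoff must lie in [0, 1)", call. = FALSE)
  if (vif_threshold <= 1) stop("vif_threshold must exceed 1", call. = FALSE)
  if (n_pseudo_absences < 1L || n_occurrences < 1L)
    stop("sample sizes must be positive", call. = FALSE)
  species <- as.data.frame(species)
  stopifnot(all(c("name", "group") %in% names(species)))
  g <- do.call(grid_spec, grid)
  structure(list(seed = as.integer(seed), grid = g, layers = layers,
                 species = species, n_occurrences = n_occurrences,
                 n_pseudo_absences = n_pseudo_absences,
                 min_year = min_year,
                 thin_cell = thin_cell %||% g$resolution,
                 k = k, weight_cutoff = weight_cutoff,
                 vif_threshold = vif_threshold, agreement = agreement,
                 learners = learners, scenarios = scenarios,
                 portfolio = portfolio, occurrences_csv = occurrences_csv),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full suitability pipeline
#'
#' Executes the stages in order — simulate (or load) occurrences, clean,
#' thin, sample pseudo-absences, VIF-screen predictors, fit the consensus
#' ensemble per species, project every scenario through its pseudo-GCMs,
#' integrate by agreement voting, and derive change, replacement and
#' portfolio summaries — writing every artifact into `out_dir` together with
#' a machine-readable run manifest (stage log, config hash, file checksums).
#' A rerun with the same config into a fresh directory is bit-identical for
#' all summary CSVs.
#'
#' Artifacts: `occurrences_*.csv`, `rejections.json`, `vif_report.json`,
#' `calibration_<species>.json`, `rasters/*.asc` (baseline suitability and
#' presence, integrated future presence per scenario), `change_summary.csv`,
#' `replacement_summary.csv`, `portfolio_summary.csv`,
#' `species_area_change.csv`, `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`stack`, `species`,
#'   `occ`, `vif`, `calibrations`, `projections`, `summaries`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "rasters"), showWarnings = FALSE)
  seed <- config$seed
  stages <- list()
  note <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1L]] <<- list(stage = stage,
                                           inputs = n_in, outputs = n_out)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", {
    stack <- generate_predictor_stack(config$grid, config$layers,
                                      seed = stage_seed(seed, "landscape"))
    species <- lapply(seq_len(nrow(config$species)), function(i) {
      nm <- config$species$name[i]
      random_virtual_species(stack, seed = stage_seed(seed,
                                                      paste0("species:", nm)),
                             name = nm)
    })
    names(species) <- config$species$name
    raw <- if (!is.null(config$occurrences_csv)) {
      read_occurrences(config$occurrences_csv)
    } else {
      do.call(rbind, lapply(species, function(sp)
        sample_occurrences(sp, stack, config$n_occurrences,
                           seed = stage_seed(seed, paste0("occ:", sp$name)))))
    }
    list(stack = stack, species = species, raw = raw)
  })
  write_occurrences(sim$raw, file.path(out_dir, "occurrences_raw.csv"))
  note("simulate", nrow(config$species), nrow(sim$raw))

  # -- clean / thin / pseudo-absences --------------------------------------
  occ <- run_stage("clean", {
    lapply(names(sim$species), function(nm) {
      clean_occurrences(sim$raw[sim$raw$species == nm, , drop = FALSE],
                        sim$stack, min_year = config$min_year)
    })
  })
  names(occ) <- names(sim$species)
  rej <- lapply(occ, function(o) as.list(attr(o, "rejections")))
  write_json_report(rej, file.path(out_dir, "rejections.json"))
  clean_tab <- do.call(rbind, lapply(occ, function(o) o$presences))
  write_occurrences(clean_tab, file.path(out_dir, "occurrences_clean.csv"))
  note("clean", nrow(sim$raw), nrow(clean_tab))

  occ <- run_stage("thin", {
    lapply(occ, function(o)
      thin_systematic(o, cell_size = config$thin_cell,
                      seed = stage_seed(seed, paste0("thin:", o$species))))
  })
  thin_tab <- do.call(rbind, lapply(occ, function(o) o$presences))
  write_occurrences(thin_tab, file.path(out_dir, "occurrences_thinned.csv"))
  note("thin", nrow(clean_tab), nrow(thin_tab))

  occ <- run_stage("pseudoabs", {
    lapply(occ, function(o)
      sample_pseudo_absences(o, sim$stack, n = config$n_pseudo_absences,
                             seed = stage_seed(seed,
                                               paste0("pa:", o$species))))
  })
  pa_tab <- do.call(rbind, lapply(names(occ), function(nm)
    cbind(species = nm, occ[[nm]]$pseudo_absences)))
  utils::write.csv(pa_tab, file.path(out_dir, "pseudo_absences.csv"),
                   row.names = FALSE)
  note("pseudoabs", length(occ), nrow(pa_tab))

  # -- VIF predictor screening ---------------------------------------------
  vif <- run_stage("vif", {
    select_predictors_vif(sim$stack, threshold = config$vif_threshold,
                          layers = config$layers,
                          seed = stage_seed(seed, "vif"))
  })
  write_json_report(
    list(retained = vif$retained, threshold = vif$threshold,
         removed = Filter(Negate(is.na),
                          vapply(vif$iterations, `[[`, character(1),
                                 "removed"))),
    file.path(out_dir, "vif_report.json"))
  note("vif", length(config$layers), length(vif$retained))

  # -- ensemble calibration ------------------------------------------------
  learners <- default_learners(config$learners)
  calibs <- run_stage("fit", {
    lapply(occ, function(o)
      fit_ensemble(o, sim$stack, layers = vif$retained,
                   learners = learners, k = config$k,
                   weight_cutoff = config$weight_cutoff,
                   seed = stage_seed(seed, paste0("fit:", o$species))))
  })
  baseline_bin <- list()
  for (nm in names(calibs)) {
    write_json_report(calibration_summary(calibs[[nm]]),
                      file.path(out_dir,
                                sprintf("calibration_%s.json", nm)))
    suit <- predict_consensus(calibs[[nm]], sim$stack)
    baseline_bin[[nm]] <- binarize(suit, calibs[[nm]]$threshold)
    write_ascii_grid(suit, sim$stack$grid,
                     file.path(out_dir, "rasters",
                               sprintf("%s_baseline_suitability.asc", nm)))
    write_ascii_grid(baseline_bin[[nm]], sim$stack$grid,
                     file.path(out_dir, "rasters",
                               sprintf("%s_baseline_presence.asc", nm)))
  }
  note("fit", length(occ), length(calibs))

  # -- scenario projection + integration -----------------------------------
  projections <- run_stage("project", {
    out <- list()
    for (sc in config$scenarios) {
      spec <- build_scenario(sc, config$layers,
                             seed = stage_seed(seed,
                                               paste0("scenario:", sc$name)))
      out[[sc$name]] <- lapply(calibs, function(cal)
        project_scenario_set(cal, sim$stack, spec,
                             agreement = config$agreement))
    }
    out
  })
  for (scn in names(projections))
    for (nm in names(projections[[scn]]))
      write_ascii_grid(projections[[scn]][[nm]]$integrated, sim$stack$grid,
                       file.path(out_dir, "rasters",
                                 sprintf("%s_%s_presence.asc", nm, scn)))
  note("project", length(calibs),
       length(projections) * length(calibs))

  # -- change / replacement / portfolio analyses ---------------------------
  summaries <- run_stage("analyze", {
    elev <- sim$stack$layers$elevation
    crops <- config$species$name[config$species$group == "crop"]
    trees <- setdiff(config$species$name, crops)
    changes <- list()
    change_rows <- list()
    for (scn in names(projections)) {
      for (nm in names(projections[[scn]])) {
        ch <- classify_change(baseline_bin[[nm]],
                              projections[[scn]][[nm]]$integrated,
                              grid = sim$stack$grid)
        changes[[scn]][[nm]] <- ch
        pct <- area_change_percent(ch)
        change_rows[[paste(scn, nm)]] <-
          data.frame(scenario = scn, species = nm,
                     loss_pct = pct[["loss"]], gain_pct = pct[["gain"]],
                     remain_pct = pct[["remain"]])
      }
    }
    change_summary <- do.call(rbind, change_rows)
    rownames(change_summary) <- NULL

    repl_rows <- list()
    if (length(crops) >= 2L) {
      for (scn in names(projections)) {
        rp <- replacement_analysis(changes[[scn]][[crops[1]]],
                                   projections[[scn]][[crops[2]]]$integrated,
                                   elevation = elev)
        overall <- data.frame(band = "all",
                              loss_cells = sum(category_mask(
                                changes[[scn]][[crops[1]]], "loss")),
                              replaceable_fraction = rp$replaceable_fraction)
        repl_rows[[scn]] <- cbind(scenario = scn,
                                  rbind(overall, rp$band_fractions))
      }
    }
    replacement_summary <- if (length(repl_rows))
      do.call(rbind, repl_rows) else NULL
    if (!is.null(replacement_summary)) rownames(replacement_summary) <- NULL

    portfolio_rows <- list()
    area_tabs <- list()
    if (length(trees) >= 1L && length(crops) >= 1L) {
      groups <- stats::setNames(config$species$group, config$species$name)
      for (scn in names(projections)) {
        tree_maps <- lapply(projections[[scn]][trees],
                            function(p) p$integrated)
        crop_area <- baseline_bin[[crops[1]]] |
          projections[[scn]][[crops[1]]]$integrated
        pf <- portfolio_richness(tree_maps, groups, crop_area,
                                 rich_total = config$portfolio$rich_total,
                                 rich_per_group =
                                   config$portfolio$rich_per_group,
                                 low_cutoff = config$portfolio$low_cutoff)
        portfolio_rows[[scn]] <- data.frame(
          scenario = scn, crop = crops[1], n_crop_cells = pf$n_crop,
          high_option_frac = pf$fractions[["high_option"]],
          low_option_frac = pf$fractions[["low_option"]],
          other_frac = pf$fractions[["other"]])
        tab <- species_area_change_table(changes[[scn]][trees], groups)
        area_tabs[[scn]] <- cbind(scenario = scn, tab)
      }
    }
    portfolio_summary <- if (length(portfolio_rows))
      do.call(rbind, portfolio_rows) else NULL
    if (!is.null(portfolio_summary)) rownames(portfolio_summary) <- NULL
    species_area <- if (length(area_tabs)) do.call(rbind, area_tabs)
                    else NULL
    if (!is.null(species_area)) rownames(species_area) <- NULL
    list(change = change_summary, replacement = replacement_summary,
         portfolio = portfolio_summary, species_area = species_area,
         changes = changes)
  })
  utils::write.csv(summaries$change,
                   file.path(out_dir, "change_summary.csv"),
                   row.names = FALSE)
  if (!is.null(summaries$replacement))
    utils::write.csv(summaries$replacement,
                     file.path(out_dir, "replacement_summary.csv"),
                     row.names = FALSE)
  if (!is.null(summaries$portfolio))
    utils::write.csv(summaries$portfolio,
                     file.path(out_dir, "portfolio_summary.csv"),
                     row.names = FALSE)
  if (!is.null(summaries$species_area))
    utils::write.csv(summaries$species_area,
                     file.path(out_dir, "species_area_change.csv"),
                     row.names = FALSE)
  note("analyze", length(calibs), nrow(summaries$change))

  # -- manifest ------------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   stages = stages,
                   files = lapply(seq_along(files), function(i)
                     list(path = files[i], md5 = unname(sums[i]))))
  write_json_report(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(stack = sim$stack, species = sim$species, occ = occ,
                 vif = vif, calibrations = calibs,
                 projections = projections, summaries = summaries,
                 manifest = manifest))
}

#' Demo fixture bundle
#'
#' A deterministic small synthetic world used by the quickstart and the test
#' suite: a 50 x 50 landscape with the nine default bioclim layers, three
#' virtual species (two crops and one agroforestry tree) and two scenarios
#' of five pseudo-GCMs each. The returned config runs end to end in well
#' under five minutes on one CPU. When `dir` is given, the landscape layers
#' (ASCII grids), raw occurrences (CSV) and scenario manifest (JSON) are
#' also written there, with an md5 manifest of every file.
#'
#' @param seed Integer seed.
#' @param dir Optional directory to write the fixture files into.
#' @return List with `config` (a [pipeline_config()]), `stack`, `species`,
#'   `occurrences` and `scenarios`; plus `manifest` when `dir` was written.
#' @export
make_demo_fixtures <- function(seed = 1L, dir = NULL) {
  config <- pipeline_config(
    seed = seed,
    grid = list(n_rows = 50L, n_cols = 50L),
    n_occurrences = 200L,
    n_pseudo_absences = 400L,
    scenarios = default_scenarios(gcm_count = 5L))
  stack <- generate_predictor_stack(config$grid, config$layers,
                                    seed = stage_seed(seed, "landscape"))
  species <- lapply(config$species$name, function(nm)
    random_virtual_species(stack,
                           seed = stage_seed(seed, paste0("species:", nm)),
                           name = nm))
  names(species) <- config$species$name
  occurrences <- do.call(rbind, lapply(species, function(sp)
    sample_occurrences(sp, stack, config$n_occurrences,
                       seed = stage_seed(seed, paste0("occ:", sp$name)))))
  rownames(occurrences) <- NULL
  scenarios <- lapply(config$scenarios, function(sc)
    build_scenario(sc, config$layers,
                   seed = stage_seed(seed, paste0("scenario:", sc$name))))
  out <- list(config = config, stack = stack, species = species,
              occurrences = occurrences, scenarios = scenarios)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(stack$layers))
      write_ascii_grid(stack$layers[[nm]], stack$grid,
                       file.path(dir, paste0(nm, ".asc")))
    write_occurrences(occurrences, file.path(dir, "occurrences.csv"))
    write_json_report(
      lapply(scenarios, function(s)
        list(name = s$name, gcm_count = s$gcm_count,
             mean_shift = as.list(s$mean_shift),
             gcm_spread = as.list(s$gcm_spread), seed = s$seed)),
      file.path(dir, "scenarios.json"))
    files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
    sums <- tools::md5sum(file.path(dir, files))
    manifest <- lapply(seq_along(files), function(i)
      list(path = files[i], md5 = unname(sums[i])))
    write_json_report(manifest, file.path(dir, "manifest.json"))
    out$manifest <- manifest
  }
  out
}
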