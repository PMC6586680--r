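#' Project a calibrated ensemble onto future climate stacks
#'
#' Applies the baseline-derived consensus model to each GCM's future stack
#' and binarises every map with the baseline presence threshold (no
#' re-thresholding per GCM: one derived suitability model, many plausible
#' futures).
#'
#' @param calib An `ensemble_calibration` (see [calibrate_ensemble()]).
#' @param gcm_stacks List of [predictor_stack()]s, one per GCM.
#' @param threshold Presence threshold; defaults to `calib$threshold`.
#' @return Named list of logical presence matrices, one per GCM.
#' @export
project_scenario <- function(calib, gcm_stacks, threshold = calib$threshold) {
  stopifnot(length(gcm_stacks) >= 1L)
  lapply(gcm_stacks, function(stk)
    binarize(predict_consensus(calib, stk), threshold))
}

#' Integrate per-GCM binary maps by agreement voting
#'
#' Collapses `g` equally weighted GCM presence/absence maps into one map
#' under a likelihood-scale agreement rule: a cell is kept as presence when
#' at least `ceil(agreement * g)` GCMs vote presence, and as absence when at
#' least that many vote absence. With the default `agreement = 0.66` and 17
#' GCMs the vote threshold is 12. Cells where neither class reaches
#' agreement are flagged in the `uncertain` raster and set to absence in the
#' integrated map (conservative: uncertain cells are not claimed suitable),
#' so the information is preserved rather than destroyed.
#'
#' @param binary_maps List of `g >= 1` logical matrices on one grid.
#' @param agreement Required agreement fraction in `(0.5, 1]`.
#' @return List with `integrated` (logical matrix), `uncertain` (logical
#'   matrix), `votes` (integer matrix of presence votes) and
#'   `vote_threshold`.
#' @export
integrate_gcm_votes <- function(binary_maps, agreement = 0.66) {
  g <- length(binary_maps)
  stopifnot(g >= 1L)
  if (!is.finite(agreement) || agreement <= 0.5 || agreement > 1)
    stop("agreement must lie in (0.5, 1]", call. = FALSE)
  d <- dim(binary_maps[[1L]])
  for (m in binary_maps)
    if (!all(dim(m) == d))
      stop("binary maps have mismatched grids", call. = FALSE)
  votes <- Reduce(`+`, lapply(binary_maps, function(m) m * 1L))
  need <- ceiling(agreement * g)
  presence <- votes >= need
  absence <- (g - votes) >= need
  uncertain <- !presence & !absence
  integrated <- presence          # uncertain cells default to absence
  integrated[is.na(votes)] <- NA
  uncertain[is.na(votes)] <- NA
  list(integrated = integrated, uncertain = uncertain,
       votes = votes, vote_threshold = as.integer(need))
}

#' Project one scenario end to end
#'
#' Convenience wrapper bundling [generate_future_stacks()],
#' [project_scenario()] and [integrate_gcm_votes()] into a `projection_set`.
#'
#' @param calib An `ensemble_calibration`.
#' @param baseline Baseline [predictor_stack()].
#' @param scenario A [scenario_spec()].
#' @param agreement Agreement fraction (default 0.66).
#' @return An object of class `projection_set`: scenario name, list of
#'   per-GCM binary maps, the integrated and uncertainty maps, votes and
#'   vote threshold.
#' @export
project_scenario_set <- function(calib, baseline, scenario,
                                 agreement = 0.66) {
  futures <- generate_future_stacks(baseline, scenario)
  maps <- project_scenario(calib, futures)
  integ <- integrate_gcm_votes(maps, agreement)
  structure(c(list(scenario = scenario$name, gcm_maps = maps), integ,
              list(agreement = agreement, grid = baseline$grid)),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf(
    "projection_set '%s': %d GCMs, vote threshold %d, %d suitable cells (%d uncertain)\n",
    x$scenario, length(x$gcm_maps), x$vote_threshold,
    sum(x$integrated, na.rm = TRUE), sum(x$uncertain, na.rm = TRUE)))
  invisible(x)
}
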