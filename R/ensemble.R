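#' Stratified k-fold assignment
#'
#' Randomly assigns training rows to `k` cross-validation bins without
#' replacement, stratified by class so presence and absence fold sizes each
#' differ by at most one and every fold holds at least one row of each class.
#'
#' @param labels 0/1 vector (1 = presence).
#' @param k Number of folds (default 4).
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: list with `k` and the
#'   integer vector `fold` (one entry per row).
#' @export
assign_folds <- function(labels, k = 4L, seed = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 2L, all(labels %in% c(0L, 1L)))
  for (cls in c(0L, 1L)) {
    if (sum(labels == cls) < k)
      stop(sprintf("class %d has %d rows; need at least k = %d",
                   cls, sum(labels == cls), k), call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = k, fold = fold), class = "fold_assignment")
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen presence scores
#' higher than a randomly chosen absence, with ties counted one half — the
#' normalised Mann-Whitney U statistic.
#'
#' @param presence_scores,absence_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' compute_auc(c(0.9, 0.8), c(0.2, 0.1))  # 1: perfect separation
#' @export
compute_auc <- function(presence_scores, absence_scores) {
  np <- length(presence_scores); na <- length(absence_scores)
  if (np == 0L || na == 0L)
    stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(presence_scores, absence_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Cross-validate a set of learners
#'
#' For every learner and fold: calibrate on the other `k - 1` folds, score
#' the held-out fold, and compute the AUC of held-out presences against
#' held-out absences. A learner that errors on any fold is assigned a mean
#' AUC of 0.5 (no discrimination, so it is typically dropped by the weight
#' cutoff later) and the failure is logged rather than aborting the species.
#'
#' @param learners List of [learner_spec()] objects (>= 2).
#' @param x Data frame of predictor rows.
#' @param y 0/1 labels.
#' @param folds A [fold_assignment()][assign_folds()].
#' @param seed Integer seed fanned out per learner and fold.
#' @return List with `auc` (learner x fold matrix), `mean_auc` (named
#'   vector), and `failures` (character vector of log lines).
#' @export
crossvalidate_learners <- function(learners, x, y, folds, seed = 1L) {
  stopifnot(length(learners) >= 2L, inherits(folds, "fold_assignment"),
            nrow(x) == length(y), length(folds$fold) == length(y))
  nms <- vapply(learners, function(l) l$name, character(1))
  auc <- matrix(NA_real_, length(learners), folds$k,
                dimnames = list(nms, paste0("fold", seq_len(folds$k))))
  failures <- character(0)
  for (i in seq_along(learners)) {
    l <- learners[[i]]
    failed <- FALSE
    for (f in seq_len(folds$k)) {
      hold <- folds$fold == f
      res <- tryCatch({
        st <- with_seed(stage_seed(seed, paste0(l$name, ":", f)),
                        l$fit(x[!hold, , drop = FALSE], y[!hold], seed))
        p <- l$predict(st, x[hold, , drop = FALSE])
        compute_auc(p[y[hold] == 1L], p[y[hold] == 0L])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- TRUE
        failures <- c(failures,
                      sprintf("%s/fold%d: %s", l$name, f, conditionMessage(res)))
        break
      }
      auc[i, f] <- res
    }
    if (failed) auc[i, ] <- NA_real_
  }
  mean_auc <- apply(auc, 1L, function(v) {
    if (anyNA(v)) 0.5 else mean(v)
  })
  list(auc = auc, mean_auc = mean_auc, failures = failures)
}

#' AUC consensus weights
#'
#' Turns mean cross-validated AUCs into consensus weights: each learner's raw
#' weight is its AUC divided by the total AUC over all learners; learners
#' whose raw weight exceeds `weight_cutoff` (default 0.05, i.e. at least a 5%
#' contribution to consensus predictivity) are selected, and their weights
#' are renormalised to sum to one.
#'
#' @param mean_aucs Named non-negative numeric vector, at least one positive.
#' @param weight_cutoff Raw-weight selection cutoff (strict `>`).
#' @return List with `raw` (sums to 1 over all learners), `selected`
#'   (character vector of names), and `final` (sums to 1 over the selected).
#' @export
compute_weights <- function(mean_aucs, weight_cutoff = 0.05) {
  stopifnot(!is.null(names(mean_aucs)), all(mean_aucs >= 0),
            any(mean_aucs > 0))
  raw <- mean_aucs / sum(mean_aucs)
  selected <- names(raw)[raw > weight_cutoff]
  if (length(selected) == 0L)
    stop("no learner passes the weight cutoff; cannot build a consensus",
         call. = FALSE)
  final <- raw[selected] / sum(raw[selected])
  list(raw = raw, selected = selected, final = final)
}

#' Maximum sensitivity + specificity threshold
#'
#' Finds the presence/absence cut-off that maximises sensitivity (true
#' positive rate) plus specificity (true negative rate) over the candidate
#' set of all unique observed scores, under the rule "presence iff score >=
#' t". When several candidates attain the maximum, the smallest is returned
#' (maximising the mapped presence area).
#'
#' @param presence_scores,absence_scores Non-empty numeric score vectors.
#' @return The threshold, one of the observed scores.
#' @export
find_threshold_maxss <- function(presence_scores, absence_scores) {
  if (length(presence_scores) == 0L || length(absence_scores) == 0L)
    stop("both score vectors must be non-empty", call. = FALSE)
  cand <- sort(unique(c(presence_scores, absence_scores)))
  ss <- vapply(cand, function(t) {
    mean(presence_scores >= t) + mean(absence_scores < t)
  }, numeric(1))
  cand[which(ss >= max(ss) - 1e-12)[1L]]
}

#' Binarise a suitability surface
#'
#' @param suitability Numeric matrix in `[0, 1]`.
#' @param threshold Presence threshold in `(0, 1)`; presence iff
#'   `suitability >= threshold`.
#' @return Logical matrix (`NA` preserved on masked cells).
#' @export
binarize <- function(suitability, threshold) {
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  suitability >= threshold
}

#' Calibrate an AUC-weighted consensus ensemble
#'
#' The full calibration recipe for one species: stratified k-fold
#' cross-validation of every learner, AUC weighting with cutoff selection,
#' refitting the selected learners on all training rows, and derivation of
#' the presence threshold by maximum sensitivity + specificity on the
#' training consensus scores.
#'
#' @param x Data frame of predictor rows (presences then absences, any
#'   order).
#' @param y 0/1 labels.
#' @param learners List of [learner_spec()]s (default [default_learners()]).
#' @param k Folds (default 4).
#' @param weight_cutoff Raw-weight selection cutoff (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `ensemble_calibration`: learner names, the
#'   AUC matrix, `mean_auc`, `raw_weights`, `selected`, `final_weights`,
#'   `threshold`, the refitted learner states, the predictor layer names,
#'   fold assignment and failure log.
#' @seealso [fit_ensemble()] for the one-call version starting from an
#'   occurrence set and a predictor stack.
#' @export
calibrate_ensemble <- function(x, y, learners = default_learners(),
                               k = 4L, weight_cutoff = 0.05, seed = 1L) {
  folds <- assign_folds(y, k = k, seed = stage_seed(seed, "folds"))
  cv <- crossvalidate_learners(learners, x, y, folds,
                               seed = stage_seed(seed, "cv"))
  w <- compute_weights(cv$mean_auc, weight_cutoff)
  nms <- vapply(learners, function(l) l$name, character(1))
  names(learners) <- nms
  fitted <- lapply(w$selected, function(nm) {
    l <- learners[[nm]]
    with_seed(stage_seed(seed, paste0("refit:", nm)), l$fit(x, y, seed))
  })
  names(fitted) <- w$selected
  calib <- structure(
    list(learner_names = nms, learners = learners[w$selected],
         layers = names(x), auc = cv$auc, mean_auc = cv$mean_auc,
         raw_weights = w$raw, selected = w$selected,
         final_weights = w$final, fitted = fitted,
         k = folds$k, folds = folds, weight_cutoff = weight_cutoff,
         seed = seed, failures = cv$failures, threshold = NA_real_),
    class = "ensemble_calibration")
  scores <- consensus_scores(calib, x)
  calib$threshold <- find_threshold_maxss(scores[y == 1L], scores[y == 0L])
  calib
}

#' @export
print.ensemble_calibration <- function(x, ...) {
  cat(sprintf("ensemble_calibration: %d/%d learners selected, threshold %.4f\n",
              length(x$selected), length(x$learner_names), x$threshold))
  tab <- data.frame(mean_auc = round(x$mean_auc, 4),
                    raw_weight = round(x$raw_weights, 4),
                    selected = names(x$mean_auc) %in% x$selected,
                    final_weight = round(
                      ifelse(names(x$mean_auc) %in% x$selected,
                             x$final_weights[names(x$mean_auc)], 0), 4))
  print(tab)
  invisible(x)
}

# weighted-average consensus scores for arbitrary predictor rows
consensus_scores <- function(calib, x) {
  p <- numeric(nrow(x))
  for (nm in calib$selected) {
    p <- p + calib$final_weights[[nm]] *
      calib$learners[[nm]]$predict(calib$fitted[[nm]], x)
  }
  clamp01(p)
}

#' One-call ensemble fit from an occurrence set
#'
#' Convenience wrapper: assembles the presence/pseudo-absence training table
#' from `occ` and `stack` over `layers` and calls [calibrate_ensemble()].
#'
#' @param occ An [occurrence_set()] with pseudo-absences.
#' @param stack A [predictor_stack()].
#' @param layers Predictor layers to use (default: all except elevation).
#' @inheritParams calibrate_ensemble
#' @return An `ensemble_calibration`.
#' @export
fit_ensemble <- function(occ, stack, layers = NULL,
                         learners = default_learners(), k = 4L,
                         weight_cutoff = 0.05, seed = 1L) {
  if (is.null(layers)) layers <- setdiff(layer_names(stack), "elevation")
  tt <- training_table(occ, stack, layers)
  calibrate_ensemble(tt$x, tt$y, learners = learners, k = k,
                     weight_cutoff = weight_cutoff, seed = seed)
}

#' Project consensus suitability onto a raster stack
#'
#' Cell-wise weighted average of the selected learners' probabilities:
#' `sum_i w_i p_i(cell)` over valid cells. By convexity the consensus lies
#' between the member predictions, hence in `[0, 1]`.
#'
#' @param calib An `ensemble_calibration`.
#' @param stack A [predictor_stack()] carrying every calibrated layer.
#' @return Suitability matrix in `[0, 1]` (`NA` on masked cells).
#' @export
predict_consensus <- function(calib, stack) {
  miss <- setdiff(calib$layers, layer_names(stack))
  if (length(miss))
    stop("stack lacks calibrated layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- valid_cell_table(stack, calib$layers)
  p <- consensus_scores(calib, tab)
  out <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  out[attr(tab, "cell_index")] <- p
  out
}

# compact JSON-serialisable view of a calibration
calibration_summary <- function(calib) {
  list(learners = calib$learner_names,
       auc = as.data.frame(calib$auc),
       mean_auc = as.list(calib$mean_auc),
       raw_weights = as.list(calib$raw_weights),
       selected = calib$selected,
       final_weights = as.list(calib$final_weights),
       threshold = calib$threshold,
       layers = calib$layers,
       failures = calib$failures)
}
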