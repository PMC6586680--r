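#' Variance inflation factors
#'
#' Computes the VIF of every variable in a table: `VIF_j = 1 / (1 - R2_j)`,
#' with `R2_j` the coefficient of determination from the ordinary
#' least-squares regression (intercept included) of variable `j` on all the
#' others. Rows with any missing value are excluded first. Perfect
#' collinearity is reported as `Inf`.
#'
#' @param values Data frame or matrix of observations x variables (>= 2
#'   variables; after removing incomplete rows there must be more rows than
#'   variables).
#' @return Named numeric vector of VIFs (all `>= 1` up to numerical
#'   tolerance).
#' @export
compute_vif <- function(values) {
  values <- as.data.frame(values)
  if (ncol(values) < 2L) stop("need at least 2 variables", call. = FALSE)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  if (nrow(values) <= ncol(values))
    stop("need more complete rows than variables", call. = FALSE)
  sds <- vapply(values, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(names(values)[sds == 0], collapse = ", "), call. = FALSE)
  x <- as.matrix(values)
  v <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(v, colnames(x))
}

#' Stepwise VIF screening of predictor layers
#'
#' Iteratively removes the single layer with the highest VIF while that VIF
#' exceeds `threshold`, the classic stepwise collinearity filter used to
#' reduce a full bioclim set to a low-collinearity subset (e.g. the nine
#' predictors retained under the conventional `VIF > 10` rule). Ties on the
#' maximum are broken by layer-name lexicographic order, so the procedure is
#' deterministic given the subsampling seed.
#'
#' VIFs are computed on a seeded random subsample of at most `sample_n` valid
#' cells (use `sample_n = Inf` for the full grid).
#'
#' @param stack A [predictor_stack()].
#' @param threshold VIF threshold (> 1; default 10).
#' @param layers Layers to screen (default: all except elevation).
#' @param sample_n Maximum number of cells used (default 10000).
#' @param seed Integer seed for the cell subsample.
#' @return An object of class `vif_report`: list with `iterations` (each a
#'   list with the named `vif` vector and the `removed` layer or `NA`) and
#'   `retained` (character vector).
#' @export
select_predictors_vif <- function(stack, threshold = 10, layers = NULL,
                                  sample_n = 10000L, seed = 1L) {
  if (threshold <= 1) stop("threshold must exceed 1", call. = FALSE)
  if (is.null(layers)) layers <- setdiff(layer_names(stack), "elevation")
  tab <- valid_cell_table(stack, layers)
  if (nrow(tab) > sample_n)
    tab <- tab[with_seed(seed, sample.int(nrow(tab), sample_n)), ,
               drop = FALSE]
  current <- sort(layers)
  iterations <- list()
  repeat {
    if (length(current) == 1L) break
    v <- compute_vif(tab[current])
    worst <- names(v)[order(-v, names(v))][1L]  # max VIF, ties by name
    if (v[[worst]] > threshold) {
      iterations <- c(iterations,
                      list(list(vif = v, removed = worst)))
      current <- setdiff(current, worst)
    } else {
      iterations <- c(iterations, list(list(vif = v, removed = NA_character_)))
      break
    }
  }
  structure(list(iterations = iterations,
                 retained = intersect(layers, current),
                 threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("vif_report: %d iteration(s), threshold %g\n",
              length(x$iterations), x$threshold))
  removed <- vapply(x$iterations, function(it) it$removed, character(1))
  removed <- removed[!is.na(removed)]
  if (length(removed)) cat("  removed:", paste(removed, collapse = ", "), "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
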