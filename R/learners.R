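#' Suitability learner contract
#'
#' A learner is the unit plugged into the consensus ensemble: anything with a
#' `fit(x, y, seed)` function returning an opaque fitted state and a
#' `predict(state, x)` function returning presence probabilities in `[0, 1]`.
#' `x` is a data.frame of predictor values, `y` a 0/1 presence vector.
#' Fitting must be deterministic given `seed`.
#'
#' @param name Learner identifier.
#' @param fit Function `(x, y, seed) -> state`.
#' @param predict Function `(state, x) -> numeric in [0, 1]`.
#' @return An object of class `learner_spec`.
#' @seealso [default_learners()]
#' @export
learner_spec <- function(name, fit, predict) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat("learner_spec:", x$name, "\n")
  invisible(x)
}

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

# linear + quadratic design, the standard parametric SDM feature set:
# species' responses to climate are typically unimodal, which a purely
# linear logistic model cannot represent
quad_features <- function(x) {
  q <- as.data.frame(lapply(x, function(v) v^2), optional = TRUE)
  names(q) <- paste0(names(x), "_sq")
  cbind(x, q)
}

#' Built-in suitability learners
#'
#' Six distinct learner families behind the [learner_spec()] contract, a
#' stand-in for the large algorithm sets of consensus SDM platforms:
#' \describe{
#'   \item{glm}{logistic regression with linear + quadratic terms (species
#'     responses to climate are typically unimodal)}
#'   \item{gam}{binomial additive model with thin-plate smooths
#'     (`mgcv`), capturing curved response shapes}
#'   \item{ridge}{ridge-regularised logistic regression on the same
#'     quadratic design (`glmnet`, `alpha = 0`), stable under collinear
#'     predictors}
#'   \item{knn}{k-nearest-neighbour presence frequency on standardised
#'     predictors (`FNN`), a local non-parametric scorer}
#'   \item{lda}{discriminant-analysis posterior on the quadratic design
#'     (`MASS`)}
#'   \item{niche_centroid}{Gaussian envelope around the presence centroid
#'     (per-predictor mean and sd of presences), a classic climate-envelope
#'     scorer}
#' }
#'
#' @param names Subset of learner names to return (default: all six).
#' @param knn_k Neighbourhood size for the knn learner.
#' @param gam_k Basis dimension per smooth for the gam learner.
#' @return Named list of [learner_spec()] objects.
#' @export
default_learners <- function(names = NULL, knn_k = 10L, gam_k = 5L) {
  all <- list(
    glm = learner_spec(
      "glm",
      fit = function(x, y, seed) {
        d <- cbind(.presence = y, quad_features(x))
        suppressWarnings(stats::glm(.presence ~ ., data = d,
                                    family = stats::binomial()))
      },
      predict = function(state, x) {
        clamp01(stats::predict(state, newdata = quad_features(x),
                               type = "response"))
      }),
    gam = learner_spec(
      "gam",
      fit = function(x, y, seed) {
        rhs <- paste(sprintf("s(%s, k = %d)", names(x), gam_k),
                     collapse = " + ")
        d <- cbind(.presence = y, x)
        suppressWarnings(mgcv::gam(
          stats::as.formula(paste(".presence ~", rhs)),
          data = d, family = stats::binomial(), method = "REML"))
      },
      predict = function(state, x) {
        clamp01(mgcv::predict.gam(state, newdata = x, type = "response"))
      }),
    ridge = learner_spec(
      "ridge",
      fit = function(x, y, seed) {
        glmnet::glmnet(as.matrix(quad_features(x)), y, family = "binomial",
                       alpha = 0, lambda = 0.01)
      },
      predict = function(state, x) {
        clamp01(stats::predict(state, newx = as.matrix(quad_features(x)),
                               type = "response", s = 0.01))
      }),
    knn = learner_spec(
      "knn",
      fit = function(x, y, seed) {
        mu <- vapply(x, mean, numeric(1))
        sd_ <- pmax(vapply(x, stats::sd, numeric(1)), 1e-12)
        list(train = scale(as.matrix(x), mu, sd_), y = y,
             mu = mu, sd = sd_, k = min(knn_k, length(y)))
      },
      predict = function(state, x) {
        q <- scale(as.matrix(x), state$mu, state$sd)
        idx <- FNN::knnx.index(state$train, q, k = state$k)
        clamp01(rowMeans(matrix(state$y[idx], nrow(idx), ncol(idx))))
      }),
    lda = learner_spec(
      "lda",
      fit = function(x, y, seed) {
        MASS::lda(quad_features(x), grouping = factor(y, levels = c(0L, 1L)))
      },
      predict = function(state, x) {
        clamp01(stats::predict(state,
                               newdata = quad_features(x))$posterior[, "1"])
      }),
    niche_centroid = learner_spec(
      "niche_centroid",
      fit = function(x, y, seed) {
        xp <- x[y == 1L, , drop = FALSE]
        list(mu = vapply(xp, mean, numeric(1)),
             sd = pmax(vapply(xp, stats::sd, numeric(1)), 1e-12))
      },
      predict = function(state, x) {
        z <- scale(as.matrix(x), state$mu, state$sd)
        clamp01(exp(-0.5 * rowSums(z^2)))
      })
  )
  if (is.null(names)) return(all)
  unknown <- setdiff(names, base::names(all))
  if (length(unknown))
    stop("unknown learner(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  all[names]
}
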