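test_that("fold assignment is stratified, balanced and seeded", {
  y <- rep(c(1L, 0L), each = 8)
  f <- assign_folds(y, k = 4, seed = 1)
  for (k in 1:4) {
    expect_equal(sum(f$fold == k & y == 1), 2)
    expect_equal(sum(f$fold == k & y == 0), 2)
  }
  expect_identical(assign_folds(y, k = 4, seed = 1)$fold, f$fold)
  expect_false(identical(assign_folds(y, k = 4, seed = 2)$fold, f$fold))

  # 9 presences over 4 folds: sizes must be {3,2,2,2} in some order
  y2 <- c(rep(1L, 9), rep(0L, 8))
  f2 <- assign_folds(y2, k = 4, seed = 3)
  expect_equal(sort(tabulate(f2$fold[y2 == 1], 4), decreasing = TRUE),
               c(3, 2, 2, 2))

  expect_error(assign_folds(c(1, 1, 1, 0, 0, 0, 0), k = 4), "class 1")
})

test_that("AUC equals brute-force pair counting", {
  expect_equal(compute_auc(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  expect_equal(compute_auc(rep(0.5, 4), rep(0.5, 3)), 0.5)
  expect_equal(compute_auc(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  expect_error(compute_auc(numeric(0), 1), "non-empty")

  set.seed(21)
  for (rep_ in 1:200) {
    np <- sample(1:10, 1); na <- sample(1:10, 1)
    p <- sample(seq(0, 1, by = 0.1), np, replace = TRUE)  # ties likely
    a <- sample(seq(0, 1, by = 0.1), na, replace = TRUE)
    expect_equal(compute_auc(p, a), auc_brute(p, a), tolerance = 1e-12)
  }
})

test_that("AUC weights follow the divide-select-renormalise recipe", {
  w <- compute_weights(c(a = 0.9, b = 0.8, c = 0.7))
  expect_equal(unname(w$raw), c(0.375, 0.8 / 2.4, 0.7 / 2.4))
  expect_setequal(w$selected, c("a", "b", "c"))
  expect_equal(w$final, w$raw)

  # ten strong learners and one weak: 0.40/9.9 < 0.05 drops the weak one
  aucs <- c(stats::setNames(rep(0.95, 10), paste0("s", 1:10)), weak = 0.40)
  w <- compute_weights(aucs)
  expect_false("weak" %in% w$selected)
  expect_equal(unname(w$final), rep(0.1, 10))

  expect_equal(unname(compute_weights(c(only = 0.8))$final), 1.0)
  expect_equal(sum(compute_weights(stats::setNames(runif(7), letters[1:7]))$raw), 1)
  expect_error(compute_weights(c(a = 0.5, b = 0.5), weight_cutoff = 0.9),
               "cutoff")
})

test_that("max sens+spec threshold equals exhaustive search", {
  expect_equal(find_threshold_maxss(c(0.9, 0.8), c(0.2, 0.1)), 0.8)
  # two maximisers at 1.5 -> smallest wins
  expect_equal(find_threshold_maxss(c(0.8, 0.4), c(0.6, 0.2)), 0.4)
  p <- c(0.7, 0.9); a <- c(0.1, 0.3)
  t_ <- find_threshold_maxss(p, a)
  expect_equal(mean(p >= t_) + mean(a < t_), 2)  # separation attains 2

  set.seed(31)
  for (rep_ in 1:200) {
    np <- sample(1:10, 1); na <- sample(1:10, 1)
    p <- round(runif(np), 2); a <- round(runif(na), 2)
    expect_identical(find_threshold_maxss(p, a), maxss_brute(p, a))
  }
})

test_that("binarisation uses the >= rule and preserves the mask", {
  m <- matrix(c(0.5, 0.4, NA, 0.6), 2, 2)
  b <- binarize(m, 0.5)
  expect_identical(b, matrix(c(TRUE, FALSE, NA, TRUE), 2, 2))
  expect_equal(sum(b, na.rm = TRUE), sum(m >= 0.5, na.rm = TRUE))
  expect_error(binarize(m, 0), "0, 1")
  expect_equal(sum(binarize(matrix(0.1, 3, 3), 0.9)), 0)
})

# deterministic stub learners for CV mechanics
stub_learner <- function(name, value) {
  learner_spec(name, fit = function(x, y, seed) value,
               predict = function(state, x) rep(state, nrow(x)))
}

test_that("cross-validation scores learners fold-wise and survives failures", {
  stk <- small_landscape(seed = 41)
  sp <- random_virtual_species(stk, seed = 42, name = "cvsp")
  occ <- clean_occurrences(sample_occurrences(sp, stk, 120, seed = 43), stk)
  occ <- sample_pseudo_absences(occ, stk, 200, seed = 44)
  tt <- ensembleSDM:::training_table(occ, stk,
                                     setdiff(names(stk$layers), "elevation"))
  folds <- assign_folds(tt$y, k = 4, seed = 45)

  flat <- stub_learner("flat", 0.5)
  oracle <- learner_spec(
    "oracle",
    fit = function(x, y, seed) sp,
    predict = function(state, x) {
      s <- rep(1, nrow(x))
      for (i in seq_len(nrow(state$niche))) {
        z <- (x[[state$niche$layer[i]]] - state$niche$mu[i]) /
          state$niche$sigma[i]
        s <- s * exp(-0.5 * z^2)
      }
      s
    })
  broken <- learner_spec("broken",
                         fit = function(x, y, seed) stop("boom"),
                         predict = function(state, x) rep(0.5, nrow(x)))

  cv <- crossvalidate_learners(list(flat, oracle, broken), tt$x, tt$y,
                               folds, seed = 1)
  expect_equal(unname(cv$mean_auc["flat"]), 0.5)
  expect_gt(cv$mean_auc[["oracle"]], 0.9)
  expect_equal(unname(cv$mean_auc["broken"]), 0.5)
  expect_match(cv$failures, "broken", all = FALSE)

  # identical learners earn identical AUC vectors
  cv2 <- crossvalidate_learners(list(stub_learner("a", 0.5),
                                     stub_learner("b", 0.5),
                                     oracle),
                                tt$x, tt$y, folds, seed = 1)
  expect_equal(unname(cv2$auc["a", ]), unname(cv2$auc["b", ]))
})

test_that("the oracle learner discriminates across many landscapes", {
  aucs <- vapply(1:10, function(seed) {
    stk <- small_landscape(seed = seed)
    # narrow niche -> separable presences vs background
    sp <- random_virtual_species(stk, seed = seed + 100, name = "v",
                                 prevalence_target = 0.02)
    occ <- clean_occurrences(sample_occurrences(sp, stk, 80,
                                                seed = seed + 200), stk)
    occ <- sample_pseudo_absences(occ, stk, 150, seed = seed + 300)
    tt <- ensembleSDM:::training_table(occ, stk,
                                       setdiff(names(stk$layers),
                                               "elevation"))
    s <- true_suitability(sp, stk)
    rc_p <- cell_of(stk$grid, occ$presences$lon, occ$presences$lat)
    rc_a <- cell_of(stk$grid, occ$pseudo_absences$lon,
                    occ$pseudo_absences$lat)
    compute_auc(s[cbind(rc_p$row, rc_p$col)], s[cbind(rc_a$row, rc_a$col)])
  }, numeric(1))
  expect_gt(median(aucs), 0.9)
})

test_that("consensus prediction is the weighted average of member maps", {
  stk <- toy_stack(list(a = matrix(rnorm(16), 4, 4)))
  fake_calib <- function(weights, values) {
    nms <- names(weights)
    learners <- lapply(seq_along(nms), function(i)
      stub_learner(nms[i], values[i]))
    names(learners) <- nms
    structure(list(layers = "a", selected = nms, final_weights = weights,
                   learners = learners,
                   fitted = stats::setNames(as.list(values), nms),
                   threshold = 0.5),
              class = "ensemble_calibration")
  }
  # two learners at 1.0 / 0.0 with weights 0.6 / 0.4 -> 0.6 everywhere
  cal <- fake_calib(c(u = 0.6, v = 0.4), c(1, 0))
  p <- predict_consensus(cal, stk)
  expect_true(all(p == 0.6))
  # unanimous members -> consensus equals the common value
  cal <- fake_calib(c(u = 0.3, v = 0.7), c(0.42, 0.42))
  expect_true(all(predict_consensus(cal, stk) == 0.42))
  # single learner with weight 1 reproduces its map
  cal <- fake_calib(c(u = 1), 0.9)
  expect_true(all(predict_consensus(cal, stk) == 0.9))
  expect_error(predict_consensus(fake_calib(c(u = 1), 0.9),
                                 toy_stack(list(zz = matrix(0, 2, 2)))),
               "lacks")
})

test_that("end-to-end calibration recovers a separable virtual species", {
  stk <- small_landscape(seed = 51, n = 40)
  sp <- random_virtual_species(stk, seed = 52, name = "cal")
  occ <- clean_occurrences(sample_occurrences(sp, stk, 150, seed = 53), stk)
  occ <- thin_systematic(occ, cell_size = stk$grid$resolution, seed = 54)
  occ <- sample_pseudo_absences(occ, stk, 300, seed = 55)
  cal <- fit_ensemble(occ, stk, seed = 56)

  expect_equal(sum(cal$raw_weights), 1)
  expect_equal(sum(cal$final_weights), 1)
  # final weights proportional to raw weights on the selected set
  expect_equal(unname(cal$final_weights),
               unname(cal$raw_weights[cal$selected] /
                        sum(cal$raw_weights[cal$selected])))
  expect_true(cal$threshold > 0 && cal$threshold < 1)

  suit <- predict_consensus(cal, stk)
  expect_true(all(suit[stk$mask] >= 0 & suit[stk$mask] <= 1))
  s <- true_suitability(sp, stk)
  expect_gt(cor(suit[stk$mask], s[stk$mask]), 0.5)

  # consensus bounded by member predictions, cell by cell
  tab <- ensembleSDM:::valid_cell_table(stk, cal$layers)
  member <- vapply(cal$selected, function(nm)
    cal$learners[[nm]]$predict(cal$fitted[[nm]], tab), numeric(nrow(tab)))
  cons <- ensembleSDM:::consensus_scores(cal, tab)
  expect_true(all(cons <= apply(member, 1, max) + 1e-12))
  expect_true(all(cons >= apply(member, 1, min) - 1e-12))
})
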