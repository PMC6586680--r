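test_that("predictor stack generation is deterministic and well-formed", {
  g <- grid_spec(50, 50, x_min = -101, y_max = 22, resolution = 2.5 / 60)
  lyr <- paste0("v", 1:5)
  a <- generate_predictor_stack(g, lyr, seed = 1)
  b <- generate_predictor_stack(g, lyr, seed = 1)
  expect_identical(a$layers, b$layers)
  expect_identical(a$mask, b$mask)
  expect_setequal(names(a$layers), c(lyr, "elevation"))
  for (m in a$layers) expect_true(all(is.finite(m[a$mask])))
  # masked cells never carry data
  for (m in a$layers) expect_true(all(is.na(m[!a$mask])))
  expect_false(identical(a$layers$v1,
                         generate_predictor_stack(g, lyr, seed = 2)$layers$v1))
})

test_that("elevation coupling makes temperature-like layers decrease upslope", {
  stk <- generate_predictor_stack(grid_spec(40, 40), seed = 3,
                                  elevation_coupling = TRUE)
  ok <- stk$mask
  for (nm in c("bio02", "bio08", "bio09")) {
    expect_lt(cor(stk$layers[[nm]][ok], stk$layers$elevation[ok]), 0)
  }
})

test_that("grid errors are caught", {
  expect_error(grid_spec(0, 10), "positive")
  expect_error(grid_spec(5, 5, resolution = -1), "resolution")
  g <- grid_spec(5, 5)
  expect_error(generate_predictor_stack(g, character(0)), "non-empty")
})

test_that("true suitability matches the Gaussian product closed form", {
  mats <- list(a = matrix(c(10, 10, 12, 50), 2, 2),
               b = matrix(c(5, 7, 5, 5), 2, 2))
  stk <- toy_stack(mats)
  sp <- virtual_species("t", data.frame(layer = c("a", "b"),
                                        mu = c(10, 5), sigma = c(2, 2)))
  s <- true_suitability(sp, stk)
  expect_equal(s[1, 1], 1)                    # both layers at centre
  expect_equal(s[2, 1], exp(-0.5))            # b one sigma off, a at centre
  expect_equal(s[1, 2], exp(-0.5))            # a one sigma off
  expect_lt(s[2, 2], 1e-40)                   # far from the niche
  expect_true(all(s >= 0 & s <= 1))
  expect_error(true_suitability(sp, toy_stack(mats["a"])), "missing")
  expect_error(virtual_species("bad", data.frame(layer = "a", mu = 0,
                                                 sigma = 0)),
               "positive")
})

test_that("occurrence sampling concentrates on suitable cells", {
  # degenerate: a single suitable cell captures every record
  m <- matrix(100, 4, 4); m[2, 3] <- 0
  stk <- toy_stack(list(a = m))
  sp <- virtual_species("pin", data.frame(layer = "a", mu = 0, sigma = 1))
  occ <- sample_occurrences(sp, stk, 25, seed = 1)
  ctr <- cell_centre(stk$grid, 2, 3)
  expect_true(all(occ$lon == ctr$lon & occ$lat == ctr$lat))

  # determinism
  stk2 <- small_landscape(seed = 4)
  sp2 <- random_virtual_species(stk2, seed = 5, name = "v")
  expect_identical(sample_occurrences(sp2, stk2, 60, seed = 9),
                   sample_occurrences(sp2, stk2, 60, seed = 9))

  # sampled cells are, on average, more suitable than the landscape
  s <- true_suitability(sp2, stk2)
  land_mean <- mean(s, na.rm = TRUE)
  for (seed in 1:10) {
    occ <- sample_occurrences(sp2, stk2, 300, seed = seed)
    su <- s[cbind(cell_of(stk2$grid, occ$lon, occ$lat)$row,
                  cell_of(stk2$grid, occ$lon, occ$lat)$col)]
    expect_gt(mean(su), land_mean)
  }

  expect_error(sample_occurrences(
    virtual_species("z", data.frame(layer = "a", mu = -1e6, sigma = 1e-3)),
    stk, 10, seed = 1), "zero")
})

test_that("cell selection frequencies follow normalised suitability x bias", {
  # chi-square goodness of fit on a 10-cell toy landscape, n = 10,000
  vals <- matrix(seq(0, 4.5, by = 0.5), 1, 10)
  stk <- toy_stack(list(a = vals), y_max = 1)
  sp <- virtual_species("g", data.frame(layer = "a", mu = 2, sigma = 1.5))
  bias <- matrix(seq(1, 2.8, by = 0.2), 1, 10)
  s <- true_suitability(sp, stk)
  w <- (s * bias) / sum(s * bias)
  occ <- sample_occurrences(sp, stk, 10000, bias = bias, seed = 11)
  col <- cell_of(stk$grid, occ$lon, occ$lat)$col
  counts <- tabulate(col, nbins = 10)
  expect_gt(stats::chisq.test(counts, p = as.numeric(w))$p.value, 0.01)
})

test_that("pseudo-GCM future stacks behave like shifted baselines", {
  stk <- small_landscape(seed = 6, layers = 3L)
  shift <- c(bio02 = 1.4, bio13 = -10)

  zero <- scenario_spec("z", shift, gcm_count = 4, gcm_spread = 0, seed = 1)
  futs <- generate_future_stacks(stk, zero)
  expect_length(futs, 4)
  expect_equal(futs[[1]]$layers$bio02, stk$layers$bio02 + 1.4)
  expect_equal(futs[[1]]$layers$bio13, stk$layers$bio13 - 10)
  expect_identical(futs[[1]]$layers, futs[[4]]$layers)

  ident <- scenario_spec("i", c(bio02 = 0), gcm_count = 2, gcm_spread = 0,
                         seed = 1)
  expect_equal(generate_future_stacks(stk, ident)[[1]]$layers, stk$layers)

  spread <- scenario_spec("s", shift, gcm_count = 17, gcm_spread = 0.3,
                          seed = 2)
  futs <- generate_future_stacks(stk, spread)
  vals <- vapply(futs, function(f) f$layers$bio02[which(stk$mask)[1]],
                 numeric(1))
  expect_length(unique(vals), 17)

  # applied deltas converge on the scenario mean shift
  many <- scenario_spec("m", shift, gcm_count = 4000, gcm_spread = 0.5,
                        seed = 3)
  d <- attr(generate_future_stacks(stk, many), "applied_deltas")
  expect_equal(colMeans(d), shift, tolerance = 0.05)

  expect_error(generate_future_stacks(
    stk, scenario_spec("bad", c(nope = 1), seed = 1)), "nope")
})
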