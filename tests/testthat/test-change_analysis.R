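rand_map <- function(nr = 8, nc = 8, p = 0.5) matrix(runif(nr * nc) < p, nr, nc)

test_that("change classification partitions baseline and future exactly", {
  # 3x3 toy: baseline 5 presences, future keeps 3 and adds 2 new
  base <- matrix(FALSE, 3, 3); base[c(1, 2, 3, 4, 5)] <- TRUE
  fut <- matrix(FALSE, 3, 3); fut[c(1, 2, 3, 8, 9)] <- TRUE
  ch <- classify_change(base, fut)
  expect_equal(sum(unclass(ch) == change_codes()["remain"]), 3)
  expect_equal(sum(unclass(ch) == change_codes()["loss"]), 2)
  expect_equal(sum(unclass(ch) == change_codes()["gain"]), 2)

  # identity: no loss, no gain
  ch0 <- classify_change(base, base)
  expect_equal(sum(unclass(ch0) == change_codes()["loss"]), 0)
  expect_equal(sum(unclass(ch0) == change_codes()["gain"]), 0)

  set.seed(91)
  for (rep_ in 1:25) {
    b <- rand_map(); f <- rand_map()
    b[1, 1] <- NA  # a masked cell must stay out of every category
    ch <- classify_change(b, f)
    m <- unclass(ch)
    cc <- change_codes()
    expect_identical((m == cc["remain"] | m == cc["loss"]) %in% TRUE,
                     b %in% TRUE)
    expect_identical((m == cc["remain"] | m == cc["gain"]) %in% TRUE &
                       !is.na(b), f %in% TRUE & !is.na(b))
    expect_true(is.na(m[1, 1]))
  }
  expect_error(classify_change(rand_map(3, 3), rand_map(4, 4)), "mismatch")
})

test_that("area change percentages are ratios of the baseline area", {
  base <- matrix(FALSE, 3, 3); base[1:5] <- TRUE
  fut <- matrix(FALSE, 3, 3); fut[c(1, 2, 3, 8, 9)] <- TRUE
  pct <- area_change_percent(classify_change(base, fut))
  expect_equal(unname(pct), c(40, 40, 60))  # loss, gain, remain
  expect_equal(pct[["loss"]] + pct[["remain"]], 100)

  same <- area_change_percent(classify_change(base, base))
  expect_equal(unname(same), c(0, 0, 100))
  gone <- area_change_percent(classify_change(base, base & FALSE))
  expect_equal(gone[["loss"]], 100)
  expect_error(area_change_percent(classify_change(base & FALSE, fut)),
               "empty")

  # cos-latitude weighting changes areas but keeps them percentages
  g <- grid_spec(3, 3, x_min = 0, y_max = 21, resolution = 7)
  pct_w <- area_change_percent(classify_change(base, fut, grid = g),
                               area_mode = "cos_lat_km2")
  expect_equal(pct_w[["loss"]] + pct_w[["remain"]], 100)
  expect_false(isTRUE(all.equal(pct_w[["loss"]], pct[["loss"]])))
})

test_that("altitudinal profiles bin change cells and report named bands", {
  base <- matrix(TRUE, 2, 2); fut <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  elev <- matrix(c(150, 150, 150, 150), 2, 2)
  pr <- altitudinal_profile(classify_change(base, fut), elev)
  occupied <- pr$bins[rowSums(pr$bins[-1]) > 0, ]
  expect_equal(nrow(occupied), 1)          # all cells in one 100 m bin
  expect_equal(occupied$elevation_lo, 100)
  expect_equal(sum(pr$bins[-1]), 4)        # bin totals == classified cells
  lowland <- pr$bands[pr$bands$band == "lowland", ]
  expect_equal(lowland$remain + lowland$loss, 4)
  expect_error(altitudinal_profile(classify_change(base, fut),
                                   matrix(0, 3, 3)), "mismatch")
})

test_that("replacement analysis partitions crop-A losses", {
  # toy: 4 loss cells for A, 3 of them inside B's future range -> 75%
  base_a <- matrix(FALSE, 3, 3); base_a[1:6] <- TRUE
  fut_a <- matrix(FALSE, 3, 3); fut_a[1:2] <- TRUE     # A loses cells 3:6
  fut_b <- matrix(FALSE, 3, 3); fut_b[c(3, 4, 5, 9)] <- TRUE
  ch_a <- classify_change(base_a, fut_a)
  rp <- replacement_analysis(ch_a, fut_b)
  expect_equal(rp$replaceable_fraction, 0.75)
  expect_equal(sum(rp$map == rp$codes["replaceable"]), 3)
  expect_equal(sum(rp$map == rp$codes["no_alternative"]), 1)

  # replaceable + no_alternative == loss, on random maps
  set.seed(92)
  for (rep_ in 1:25) {
    b <- rand_map(); f <- rand_map(); fb <- rand_map()
    ch <- classify_change(b, f)
    rp <- replacement_analysis(ch, fb)
    loss <- unclass(ch) == change_codes()["loss"]
    expect_identical(rp$map == rp$codes["replaceable"] |
                       rp$map == rp$codes["no_alternative"], loss)
  }

  # degenerate futures
  rp0 <- replacement_analysis(ch_a, fut_b & FALSE)
  expect_equal(sum(rp0$map == rp0$codes["replaceable"]), 0)
  expect_equal(sum(rp0$map == rp0$codes["no_alternative"]), 4)
  rp1 <- replacement_analysis(ch_a, !fut_a)  # B covers all of A's losses
  expect_equal(rp1$replaceable_fraction, 1)

  # per-band fractions
  elev <- matrix(rep(c(100, 500, 2000), each = 3), 3, 3)
  rpb <- replacement_analysis(ch_a, fut_b, elevation = elev)
  expect_true(all(rpb$band_fractions$replaceable_fraction >= 0 |
                    is.na(rpb$band_fractions$replaceable_fraction)))
})

test_that("portfolio richness classifies crop cells by species options", {
  # 5 cells engineered with richness 31-balanced, 31-unbalanced, 10, 3, 0
  nr <- 1; nc <- 5
  groups <- stats::setNames(rep(c("fruit", "n_fixing", "timber"),
                                c(11, 11, 11)), paste0("sp", 1:33))
  maps <- list()
  for (i in 1:33) maps[[paste0("sp", i)]] <- matrix(FALSE, nr, nc)
  # cell 1: 31 species, >=10 per group (11/10/10)
  for (i in c(1:11, 12:21, 23:32)) maps[[paste0("sp", i)]][1, 1] <- TRUE
  # cell 2: 31 species but unbalanced (11/11/9)
  for (i in c(1:11, 12:22, 24:32)) maps[[paste0("sp", i)]][1, 2] <- TRUE
  # cell 3: 10 species; cell 4: 3 species; cell 5: none
  for (i in 1:10) maps[[paste0("sp", i)]][1, 3] <- TRUE
  for (i in 1:3) maps[[paste0("sp", i)]][1, 4] <- TRUE
  crop <- matrix(TRUE, nr, nc)
  pf <- portfolio_richness(maps, groups, crop)
  expect_equal(as.numeric(pf$total), c(31, 31, 10, 3, 0))
  cls <- as.numeric(pf$classes)
  expect_equal(sum(cls == pf$codes["high_option"]), 1)   # cell 1 only
  expect_equal(sum(cls == pf$codes["low_option"]), 2)    # cells 4 and 5
  expect_equal(unname(pf$fractions["high_option"]), 0.2)
  expect_equal(unname(pf$fractions["low_option"]), 0.4)
  expect_equal(sum(pf$fractions), 1)
  expect_error(portfolio_richness(maps, groups[-1], crop), "group")
})

test_that("species area-change table counts winners and losers", {
  mk_change <- function(n_base, pct) {
    base <- matrix(FALSE, 10, 10); base[seq_len(n_base)] <- TRUE
    n_fut <- round(n_base * (1 + pct / 100))
    fut <- matrix(FALSE, 10, 10); fut[seq_len(n_fut)] <- TRUE
    classify_change(base, fut)
  }
  shifts <- c(-60, -40, -20, -16, -10, 0, 10, 16, 20, 40)
  maps <- lapply(shifts, function(p) mk_change(50, p))
  names(maps) <- paste0("sp", seq_along(shifts))
  groups <- stats::setNames(rep("fruit", 10), names(maps))
  tab <- species_area_change_table(maps, groups)
  expect_equal(sort(tab$pct_change), sort(shifts))
  counts <- attr(tab, "big_change_counts")
  expect_equal(counts$n_loss_gt, 4)   # -60, -40, -20, -16
  expect_equal(counts$n_gain_gt, 3)   # 16, 20, 40

  # all-stable species -> zero percent change everywhere
  stable <- lapply(1:3, function(i) mk_change(30, 0))
  names(stable) <- paste0("s", 1:3)
  tab0 <- species_area_change_table(
    stable, stats::setNames(rep("timber", 3), names(stable)))
  expect_true(all(tab0$pct_change == 0))
  c0 <- attr(tab0, "big_change_counts")
  expect_equal(c0$n_loss_gt + c0$n_gain_gt, 0)

  # empty baseline recorded as undefined, excluded from counts
  empty <- classify_change(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2))
  tabu <- species_area_change_table(
    list(a = empty, b = mk_change(20, -50)),
    c(a = "fruit", b = "fruit"))
  expect_true(is.na(tabu$pct_change[tabu$species == "a"]))
  expect_identical(attr(tabu, "undefined"), "a")
  expect_equal(attr(tabu, "big_change_counts")$n_loss_gt, 1)
})
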