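# Independent brute-force oracles and small fixture builders.
# Oracles deliberately avoid the implementation paths they check.

# AUC by explicit pair counting (ties count one half)
auc_brute <- function(pres, abs_) {
  tot <- 0
  for (p in pres) for (a in abs_)
    tot <- tot + (p > a) + 0.5 * (p == a)
  tot / (length(pres) * length(abs_))
}

# max sens+spec threshold by exhaustive search, smallest maximiser
maxss_brute <- function(pres, abs_) {
  cand <- sort(unique(c(pres, abs_)))
  best <- -Inf; best_t <- NA_real_
  for (t in cand) {
    ss <- mean(pres >= t) + mean(abs_ < t)
    if (ss > best + 1e-12) { best <- ss; best_t <- t }
  }
  best_t
}

# VIF via explicit normal equations
vif_oracle <- function(df) {
  x <- as.matrix(df)
  sapply(seq_len(ncol(x)), function(j) {
    a <- cbind(1, x[, -j, drop = FALSE])
    y <- x[, j]
    beta <- solve(t(a) %*% a, t(a) %*% y)
    rss <- sum((y - a %*% beta)^2)
    tss <- sum((y - mean(y))^2)
    1 / (1 - (1 - rss / tss))
  })
}

# agreement voting by per-cell loops
votes_brute <- function(maps, agreement) {
  g <- length(maps)
  need <- ceiling(agreement * g)
  d <- dim(maps[[1]])
  integrated <- matrix(NA, d[1], d[2])
  uncertain <- matrix(NA, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- sum(vapply(maps, function(m) m[i, j], logical(1)))
    pres <- v >= need
    abs_ok <- (g - v) >= need
    integrated[i, j] <- pres
    uncertain[i, j] <- !pres && !abs_ok
  }
  list(integrated = integrated, uncertain = uncertain)
}

# uniform-valued toy stack builder: one layer per supplied matrix
toy_stack <- function(mats, x_min = 0, y_max = 10, resolution = 1,
                      mask = NULL) {
  m1 <- mats[[1]]
  g <- grid_spec(nrow(m1), ncol(m1), x_min = x_min, y_max = y_max,
                 resolution = resolution)
  predictor_stack(g, mats, mask)
}

# small spatially structured landscape for model tests
small_landscape <- function(seed = 1L, n = 30L, layers = 4L) {
  generate_predictor_stack(
    grid_spec(n, n, x_min = -101, y_max = 22, resolution = 2.5 / 60),
    layers = paste0("bio", sprintf("%02d", c(2, 8, 13, 15, 18, 19)[seq_len(layers)])),
    seed = seed)
}
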