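test_that("time-delay embedding lays out lags and flags missing rows", {
  x <- as.numeric(1:6)
  e1 <- embed_series(x, 1)
  expect_equal(as.numeric(e1$block), x)
  e3 <- embed_series(x, 3, 1)
  expect_equal(e3$block[3, ], c(3, 2, 1))
  expect_equal(e3$valid, 3:6)

  # one missing value invalidates exactly the E rows that touch it
  y <- as.numeric(1:10); y[5] <- NA
  e <- embed_series(y, 3, 1)
  expect_equal(setdiff(3:10, e$valid), 5:7)

  expect_error(embed_series(1:3, 5), "insufficient data")
})

test_that("simplex matches the brute-force nearest-neighbour oracle", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(60:200, 1)
    E <- sample(2:4, 1)
    x <- as.numeric(arima.sim(list(ar = 0.7), n))
    got <- simplex_forecast(x, E)
    want <- oracle_simplex(x, E)
    expect_equal(got$predictions, want$predictions, tolerance = 1e-12)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
  }
})

test_that("exclusion radius keeps neighbours away from the target time", {
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = 0.8), 150))
  for (r in c(0L, 5L, 12L)) {
    emb <- embed_series(zscore(x), 3)
    nb <- planknet:::simplex_neighbours_cpp(emb$block, emb$valid, emb$valid,
                                            4L, r)
    dt <- abs(nb$ind - emb$valid)
    expect_true(all(dt > r, na.rm = TRUE))
  }
  # and agrees with the oracle under exclusion
  got <- simplex_forecast(x, 2, exclusion_radius = 6)
  want <- oracle_simplex(x, 2, exclusion_radius = 6)
  expect_equal(got$predictions, want$predictions, tolerance = 1e-12)
})

test_that("forecast skill behaves on canonical fixtures", {
  x <- logistic_map(500)
  expect_gt(simplex_forecast(x, 2)$rho, 0.99)
  expect_equal(as.integer(select_E(x, 2:8)), 2L)

  set.seed(12)
  z <- rnorm(500)
  expect_lt(abs(simplex_forecast(z, 3)$rho), 0.2)

  # pure 12-month sinusoid embeds in few dimensions
  s <- sin(2 * pi * (1:300) / 12)
  expect_lte(as.integer(select_E(s, 2:8)), 3L)

  expect_equal(as.integer(select_E(x, 4L)), 4L)  # single-E range
})

test_that("an exact duplicate state dominates the prediction", {
  # exactly periodic series: every state recurs, nearest distance 0,
  # so predictions equal the realized next values
  x <- rep(c(0.2, 0.9, 0.4, 0.7, 0.1, 0.8), 20)
  sf <- simplex_forecast(x, 2)
  expect_equal(sf$rho, 1, tolerance = 1e-12)
})

test_that("s-map at theta 0 equals global least squares", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(40:120, 1)
    d <- sample(2:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- as.numeric(X %*% rnorm(d) + rnorm(n, 0, 0.2))
    fit <- smap_forecast(X, y, theta = 0, exclusion_radius = -1)
    ref <- lm(y ~ X)
    expect_lt(max(abs(fit$coefficients[1, ] - coef(ref))), 1e-8)
    expect_lt(max(abs(fit$predictions - fitted(ref))), 1e-8)
  }
})

test_that("s-map recovers an exactly linear response for any theta", {
  set.seed(14)
  X <- matrix(rnorm(120), 60, 2)
  y <- 2 * X[, 1] + 1
  for (th in c(0, 0.5, 2, 8)) {
    fit <- smap_forecast(X, y, theta = th, exclusion_radius = -1)
    expect_equal(max(abs(fit$predictions - y)), 0, tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[, 2]), rep(2, 60), tolerance = 1e-8)
  }
})

test_that("state dependence raises cross-validated s-map skill", {
  # Ricker-pair fixture: response depends nonlinearly on state
  rp <- ricker_pair(300, seed = 15)
  emb <- embed_series(zscore(rp$b), 3)
  X <- emb$block[emb$valid, ]
  y <- shift_series(zscore(rp$b), 1)[emb$valid]
  keep <- is.finite(y)
  f0 <- smap_forecast(X[keep, ], y[keep], theta = 0,
                      exclusion_radius = 0, lib_time = emb$valid[keep])
  f2 <- smap_forecast(X[keep, ], y[keep], theta = 2,
                      exclusion_radius = 0, lib_time = emb$valid[keep])
  expect_gte(f2$rho, f0$rho)
})

test_that("cross-map skill is asymmetric under unidirectional coupling", {
  cfg <- two_species_config(seed = 3)
  tab <- generate_foodweb(cfg)$table
  Eb <- as.integer(select_E(tab$G1, 2:8))
  Ea <- as.integer(select_E(tab$P1, 2:8))
  true_dir <- cross_map(tab$G1, tab$P1, Eb, tp = -1)   # G1 xmap P1: P1 -> G1
  false_dir <- cross_map(tab$P1, tab$G1, Ea, tp = -1)
  expect_gt(true_dir$rho, false_dir$rho)

  # self cross-map is as skilful as self-prediction
  self_cm <- cross_map(tab$G1, tab$G1, Eb, tp = 0)
  expect_gt(self_cm$rho, 0.9)

  # independent white noise cross-maps at chance level
  set.seed(16)
  r1 <- rnorm(400); r2 <- rnorm(400)
  expect_lt(abs(cross_map(r1, r2, 3, tp = 0)$rho), 0.25)
})

test_that("cross-map skill is invariant to affine driver rescaling", {
  cfg <- two_species_config(seed = 4)
  tab <- generate_foodweb(cfg)$table
  base <- cross_map(tab$G1, tab$P1, 4, tp = -1)
  scaled <- cross_map(tab$G1, 3.2 * tab$P1 + 17, 4, tp = -1)
  expect_equal(base$rho, scaled$rho, tolerance = 1e-10)
})
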