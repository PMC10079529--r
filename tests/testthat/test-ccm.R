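test_that("seasonal surrogates preserve the monthly climatology exactly", {
  set.seed(20)
  n <- 120
  x <- sin(2 * pi * (1:n) / 12) + rnorm(n, 0, 0.5)
  surr <- seasonal_surrogates(x, 25, seed = 1)
  month <- ((seq_len(n) - 1) %% 12) + 1
  for (s in c(1, 13, 25)) {
    expect_equal(tapply(surr[, s], month, mean), tapply(x, month, mean))
    # within-month value sets are conserved (pure permutation)
    for (m in c(1, 6, 12)) {
      expect_setequal(surr[month == m, s], x[month == m])
    }
  }
  # pure periodic series has zero anomalies: surrogates identical
  p <- rep(sin(2 * pi * (1:12) / 12), 10)
  sp <- seasonal_surrogates(p, 5, seed = 2)
  expect_equal(as.numeric(sp), rep(p, 5))
  # missing values stay missing
  xm <- x; xm[c(5, 40)] <- NA
  sm <- seasonal_surrogates(xm, 5, seed = 3)
  expect_true(all(is.na(sm[c(5, 40), ])))
  expect_true(all(is.finite(sm[-c(5, 40), ])))
  expect_error(seasonal_surrogates(x[1:20], 5), "24 months")
})

test_that("phase-randomized surrogates preserve the anomaly spectrum", {
  set.seed(19)
  n <- 240
  month <- ((seq_len(n) - 1) %% 12) + 1
  x <- sin(2 * pi * (1:n) / 12) + as.numeric(arima.sim(list(ar = 0.8), n))
  surr <- seasonal_surrogates(x, 20, seed = 1, method = "phase")
  anom <- function(v) v - ave(v, month)
  # anomaly variance (total spectral power) preserved per surrogate
  va <- apply(surr, 2, function(v) var(anom(v)))
  expect_equal(va, rep(var(anom(x)), 20), tolerance = 1e-6)
  # lag-1 anomaly autocorrelation preserved on average, unlike shuffling
  ac1 <- function(v) { a <- anom(v); cor(a[-1], a[-n]) }
  expect_equal(mean(apply(surr, 2, ac1)), ac1(x), tolerance = 0.15)
  # climatology preserved
  expect_equal(tapply(surr[, 1], month, mean), tapply(x, month, mean),
               tolerance = 1e-10)
  expect_error(seasonal_surrogates(c(x, NA), 5, method = "phase"),
               "gap-free")
})

test_that("surrogates destroy interannual anomaly autocorrelation", {
  set.seed(21)
  n <- 240
  month <- ((seq_len(n) - 1) %% 12) + 1
  x <- sin(2 * pi * (1:n) / 12) + as.numeric(arima.sim(list(ar = 0.9), n))
  anom <- function(v) v - ave(v, month)
  ac1 <- function(v) { a <- anom(v); cor(a[-1], a[-n]) }
  surr <- seasonal_surrogates(x, 100, seed = 4)
  ac_orig <- ac1(x)
  ac_surr <- mean(apply(surr, 2, ac1))
  expect_gt(ac_orig, 0.6)
  expect_lt(abs(ac_surr), 0.15)
})

test_that("significance and strength follow the 95 percent beat rule", {
  centres <- 1:4
  local <- data.frame(window_centre = centres,
                      local_rho = c(0.8, 0.2, 0.5, NA))
  surr <- matrix(0.3, 4, 100)
  out <- significance_and_strength(local, surr)
  expect_true(out$significant[1])
  expect_equal(out$strength[1], 0.5)          # 0.8 - mean(0.3)
  expect_false(out$significant[2])            # below every surrogate
  expect_equal(out$strength[2], 0)
  expect_true(out$skipped[4])
  expect_true(is.na(out$strength[4]))

  # ties count as failures: exactly equal never beats
  tie <- significance_and_strength(
    data.frame(window_centre = 1, local_rho = 0.3),
    matrix(0.3, 1, 100))
  expect_false(tie$significant)

  # negative corrected strength floors at zero
  neg <- significance_and_strength(
    data.frame(window_centre = 1, local_rho = 0.4),
    matrix(c(rep(0.39, 96), rep(0.9, 4)), 1, 100))
  expect_true(neg$significant)
  expect_gte(neg$strength, 0)

  expect_error(significance_and_strength(local, matrix(0.3, 4, 10)),
               "too small")
  expect_error(significance_and_strength(local, matrix(0.3, 3, 100)),
               "misaligned")
})

test_that("convergence test accepts coupled pairs and validates input", {
  cfg <- two_species_config(seed = 5)
  tab <- generate_foodweb(cfg)$table
  E <- as.integer(select_E(tab$G1, 2:8))
  ct <- convergence_test(tab$G1, tab$P1, E, seed = 9)
  expect_true(ct$convergent)
  expect_length(ct$rho_small, 100)
  expect_gt(mean(ct$rho_large), mean(ct$rho_small))

  expect_error(convergence_test(tab$G1, tab$P1, E, frac_small = 0.5,
                                frac_large = 0.5), "frac_small")
  expect_error(convergence_test(tab$G1[1:40], tab$P1[1:40], 8),
               "insufficient")
})

test_that("convergence screening separates coupled from independent pairs", {
  # Size on independent white noise is liberal (the subset skills are
  # strongly dependent, inflating the t statistic): Monte-Carlo puts the
  # false-positive rate near 0.17, far below the near-certain detection
  # of genuinely coupled pairs.
  set.seed(22)
  fp <- vapply(1:60, function(i) {
    a <- rnorm(240); b <- rnorm(240)
    convergence_test(a, b, 3, n_subsets = 50, seed = i)$convergent
  }, logical(1))
  expect_lte(mean(fp), 0.35)

  power <- vapply(1:10, function(s) {
    tab <- generate_foodweb(two_species_config(seed = 200 + s))$table
    E <- as.integer(select_E(tab$G1, 2:6))
    convergence_test(tab$G1, tab$P1, E, n_subsets = 50,
                     seed = 300 + s)$convergent
  }, logical(1))
  expect_gte(mean(power), 0.9)
  expect_gt(mean(power), mean(fp))
})

test_that("moving-window skill tracks a coupling change point", {
  rp <- ricker_pair(480, switch_off_at = 240, seed = 23, noise = 0.05)
  E <- as.integer(select_E(rp$b, 2:8))
  lr <- local_rho(rp$b, rp$a, E, window = 60)
  early <- lr$local$local_rho[lr$local$window_centre < 200]
  late <- lr$local$local_rho[lr$local$window_centre > 300]
  expect_gt(mean(early, na.rm = TRUE), mean(late, na.rm = TRUE))
})

test_that("a full-span window reproduces the whole-series skill", {
  rp <- ricker_pair(200, seed = 24)
  E <- 3
  cm <- cross_map(rp$b, rp$a, E, tp = -1)
  ok <- is.finite(cm$observed) & is.finite(cm$predictions)
  span <- max(which(ok)) - min(which(ok)) + 1
  lr <- local_rho(rp$b, rp$a, E, window = span)
  expect_equal(nrow(lr$local), 1)
  expect_equal(lr$local$local_rho,
               cor(cm$observed[ok], cm$predictions[ok]),
               tolerance = 1e-12)
  # stationary coupled pair: window skills fluctuate around whole-series rho
  lr60 <- local_rho(rp$b, rp$a, E, window = 60)
  expect_lt(abs(mean(lr60$local$local_rho, na.rm = TRUE) - lr$whole_rho), 0.2)
})

test_that("window centres follow the stamp arithmetic", {
  rp <- ricker_pair(200, seed = 25)
  lr <- local_rho(rp$b, rp$a, 3, window = 60)
  ok <- is.finite(lr$cm$observed) & is.finite(lr$cm$predictions)
  first_pred <- min(which(ok))
  expect_equal(lr$local$window_centre[1], first_pred + 29)
  expect_equal(diff(lr$local$window_centre), rep(1, nrow(lr$local) - 1))
})

test_that("build_network recovers structure and is stable to node removal", {
  cfg <- synthetic_config(n_guilds = 5, n_months = 300, seed = 26)
  tab <- generate_foodweb(cfg)$table
  g <- synthetic_guild_graph(cfg)
  config <- run_config(n_surrogates = 30, n_convergence_subsets = 50,
                       E_range = 2:6, master_seed = 13)
  net <- build_network(tab, g, config)
  expect_s3_class(net, "ccm_network")
  expect_equal(nrow(net$meta), nrow(g$links))
  expect_true(all(net$links$strength[!net$links$skipped] >= 0, na.rm = TRUE))
  expect_true(all(net$links$strength[!net$links$skipped] <= 2, na.rm = TRUE))
  # strength zero wherever not significant
  ns <- !net$links$significant & !net$links$skipped
  expect_true(all(net$links$strength[ns] == 0))
  # non-convergent pairs carry all-zero strength
  for (i in which(!net$meta$convergent)) {
    sel <- net$links$driver == net$meta$driver[i] &
      net$links$driven == net$meta$driven[i]
    expect_true(all(net$links$strength[sel] == 0, na.rm = TRUE))
    expect_true(all(!net$links$significant[sel]))
  }

  # removing one node leaves other pairs' results unchanged
  keep <- setdiff(g$nodes$guild, "Z1")
  g2 <- guild_graph(g$nodes[g$nodes$guild %in% keep, ],
                    g$links[g$links$driver %in% keep &
                            g$links$driven %in% keep, ])
  net2 <- build_network(tab, g2, config)
  shared <- paste(net2$links$driver, net2$links$driven)
  sub1 <- net$links[paste(net$links$driver, net$links$driven) %in% shared, ]
  expect_equal(net2$links$strength, sub1$strength)
  expect_equal(net2$links$significant, sub1$significant)

  # empty candidate set gives an empty result
  g0 <- guild_graph(g$nodes, g$links[0, ])
  net0 <- build_network(tab, g0, config)
  expect_equal(nrow(net0$meta), 0)

  expect_error(build_network(tab[, 1:3], g, config), "schema error")
})

test_that("driver effects are detected for sensitive guilds only", {
  cfg <- synthetic_config(n_guilds = 4, n_months = 360, seed = 27,
                          temp_noise_sd = 0.8)
  d <- generate_drivers(cfg)
  fw <- generate_foodweb(cfg, d)
  config <- run_config(n_surrogates = 30, n_convergence_subsets = 50,
                       E_range = 2:6, master_seed = 17)
  # P1 has hard-coded temperature sensitivity in the default config
  expect_true(cfg$driver_effects["P1", "temperature"] > 0)
  eff_sens <- driver_effect(fw$table$P1, d$temperature, config, seed = 31)
  # G2 is decoupled from phosphate
  expect_true(cfg$driver_effects["G2", "phosphate"] == 0)
  eff_nosens <- driver_effect(fw$table$G2, d$phosphate, config, seed = 32)
  expect_gt(eff_sens$effect, eff_nosens$effect)
  expect_lt(eff_nosens$effect, 0.1)
})

test_that("feedback test flags coupled drivers and spares independent ones", {
  config <- run_config(n_surrogates = 30, n_convergence_subsets = 50,
                       E_range = 2:6, master_seed = 19)
  # coupled: phosphate responds to temperature anomalies
  cfg <- synthetic_config(seed = 9, temp_phos_coupling = -0.8,
                          temp_trend = 0, phosphate_decline = 0,
                          temp_noise_sd = 1)
  d <- generate_drivers(cfg)
  fb <- feedback_test(d$temperature, d$phosphate, config,
                      c("temperature", "phosphate"))
  expect_true(any(fb$significant))

  # independent drivers: neither direction significant
  for (s in c(101, 102)) {
    cfg0 <- synthetic_config(seed = s, temp_phos_coupling = 0,
                             temp_trend = 0, phosphate_decline = 0,
                             temp_noise_sd = 1)
    d0 <- generate_drivers(cfg0)
    fb0 <- feedback_test(d0$temperature, d0$phosphate, config,
                         c("temperature", "phosphate"))
    expect_false(any(fb0$significant))
  }

  # identical series: both directions convergent (degenerate case)
  x <- d$temperature
  fbx <- feedback_test(x, x + 1e-9 * seq_along(x), config, c("a", "b"))
  expect_true(all(fbx$convergent))
})
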