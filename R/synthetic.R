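#' Configuration for the synthetic lake food-web simulator
#'
#' Builds the parameter set for a seasonally forced multispecies Ricker
#' simulation with environmental driver modulation.  Defaults emulate the
#' monitoring setting the package targets: 8 trophic guilds observed
#' monthly for 40 years (480 months) under a warming ramp and an
#' exponential phosphate decline (re-oligotrophication), with low
#' process and observation noise.
#'
#' Guilds are organised in three trophic levels (producers, grazers,
#' predators).  The coupling matrix holds signed per-capita interaction
#' coefficients `coupling[i, j]` = effect of guild `j`'s abundance on
#' guild `i`'s growth; its diagonal is the self-regulation term
#' (`-growth_rates`), so an uncoupled guild has fixed point 1 in the
#' absence of forcing.  Off-diagonal structure defaults to a
#' predator-prey web: prey -> predator +0.1 (bottom-up), predator ->
#' prey -0.25 (top-down).
#'
#' @param n_guilds number of guilds (>= 2).
#' @param n_months number of monthly samples (>= 120).
#' @param coupling optional `n_guilds x n_guilds` signed coefficient
#'   matrix (diagonal = self-regulation).  Default: the built-in web.
#' @param growth_rates per-guild intrinsic rates; defaults in the chaotic
#'   Ricker range (2.5-3.1).
#' @param seasonal_amplitude per-guild dimensionless amplitude of the
#'   12-month multiplicative forcing on the growth rate.
#' @param seasonal_phase per-guild phase (months); grazers lag producers.
#' @param driver_effects `n_guilds x 2` matrix of sensitivities to the
#'   standardized temperature and phosphate anomalies.
#' @param temp_mean,temp_seasonal_amp water-column mean temperature (degC)
#'   and annual amplitude.
#' @param temp_trend warming ramp, degC per decade.
#' @param temp_noise_sd sd of the AR(1) temperature anomaly (degC).
#' @param phos_baseline initial phosphate level (ug/L).
#' @param phos_seasonal_amp relative annual amplitude of phosphate.
#' @param phosphate_decline fractional decline per decade (0.4 means the
#'   deseasonalized baseline drops 40\% every 120 months).
#' @param phos_noise_sd sd of the AR(1) log-phosphate anomaly.
#' @param temp_phos_coupling effect of the temperature anomaly (degC) on
#'   log phosphate (warming-driven stratification reduces mixing, hence
#'   negative by default).
#' @param process_noise_sd sd of the Gaussian noise in the Ricker
#'   exponent.
#' @param obs_noise_sd sd of multiplicative lognormal observation noise
#'   (plankton counts are positive and right-skewed).
#' @param missing_frac fraction of guild-months blanked at random to
#'   exercise gap handling; default 0.
#' @param seed integer; fully determines the simulation.
#' @return object of class `synthetic_config`.
#' @seealso [generate_drivers()], [generate_foodweb()],
#'   [two_species_config()], [synthetic_guild_graph()]
#' @export
synthetic_config <- function(n_guilds = 8L,
                             n_months = 480L,
                             coupling = NULL,
                             growth_rates = NULL,
                             seasonal_amplitude = NULL,
                             seasonal_phase = NULL,
                             driver_effects = NULL,
                             temp_mean = 10,
                             temp_seasonal_amp = 4,
                             temp_trend = 0.3,
                             temp_noise_sd = 0.3,
                             phos_baseline = 60,
                             phos_seasonal_amp = 0.15,
                             phosphate_decline = 0.4,
                             phos_noise_sd = 0.1,
                             temp_phos_coupling = -0.3,
                             process_noise_sd = 0.02,
                             obs_noise_sd = 0.05,
                             missing_frac = 0,
                             seed = 1L) {
  if (n_guilds < 2) stop("invalid config: n_guilds must be >= 2")
  if (n_months < 120) stop("invalid config: n_months must be >= 120")
  for (f in c("temp_noise_sd", "phos_noise_sd", "process_noise_sd", "obs_noise_sd")) {
    v <- get(f)
    if (!is.finite(v) || v < 0) stop("invalid config: ", f, " must be >= 0")
  }
  if (!(phosphate_decline >= 0 && phosphate_decline < 1))
    stop("invalid config: phosphate_decline must be in [0, 1)")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("invalid config: missing_frac must be in [0, 1)")

  roles <- guild_roles(n_guilds)
  if (is.null(growth_rates)) {
    base_r <- c(producer = 3.0, grazer = 2.7, predator = 2.5)
    growth_rates <- base_r[roles$level] + 0.1 * (seq_len(n_guilds) %% 3 - 1)
  }
  if (length(growth_rates) != n_guilds)
    stop("invalid config: growth_rates must have length n_guilds")
  if (is.null(seasonal_amplitude)) {
    base_a <- c(producer = 0.3, grazer = 0.2, predator = 0.1)
    seasonal_amplitude <- unname(base_a[roles$level])
  }
  if (length(seasonal_amplitude) == 1) seasonal_amplitude <- rep(seasonal_amplitude, n_guilds)
  if (length(seasonal_amplitude) != n_guilds)
    stop("invalid config: seasonal_amplitude must have length n_guilds")
  if (is.null(seasonal_phase)) {
    lag <- c(producer = 0, grazer = 1, predator = 2)
    seasonal_phase <- unname(lag[roles$level])
  }
  if (is.null(coupling)) coupling <- default_coupling(roles, growth_rates)
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == n_guilds))
    stop("coupling matrix has wrong shape: expected ", n_guilds, " x ", n_guilds)
  if (is.null(driver_effects)) {
    driver_effects <- matrix(0, n_guilds, 2,
                             dimnames = list(roles$guild, c("temperature", "phosphate")))
    prod_idx <- which(roles$level == "producer")
    driver_effects[prod_idx, "phosphate"] <- 0.2
    driver_effects[prod_idx[1], "temperature"] <- 0.2
    gr_idx <- which(roles$level == "grazer")
    if (length(gr_idx)) driver_effects[gr_idx[1], "temperature"] <- 0.15
  }
  driver_effects <- as.matrix(driver_effects)
  if (!all(dim(driver_effects) == c(n_guilds, 2)))
    stop("invalid config: driver_effects must be n_guilds x 2")

  structure(list(
    n_guilds = as.integer(n_guilds), n_months = as.integer(n_months),
    guilds = roles$guild, levels = roles$level,
    coupling = coupling, growth_rates = as.numeric(growth_rates),
    seasonal_amplitude = as.numeric(seasonal_amplitude),
    seasonal_phase = as.numeric(seasonal_phase),
    driver_effects = driver_effects,
    temp_mean = temp_mean, temp_seasonal_amp = temp_seasonal_amp,
    temp_trend = temp_trend, temp_noise_sd = temp_noise_sd,
    phos_baseline = phos_baseline, phos_seasonal_amp = phos_seasonal_amp,
    phosphate_decline = phosphate_decline, phos_noise_sd = phos_noise_sd,
    temp_phos_coupling = temp_phos_coupling,
    process_noise_sd = process_noise_sd, obs_noise_sd = obs_noise_sd,
    missing_frac = missing_frac, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Assign guilds to three trophic levels: ~3/8 producers, ~3/8 grazers,
# remainder invertebrate predators (none for very small webs).
guild_roles <- function(n_guilds) {
  np <- max(1L, round(n_guilds * 3 / 8))
  ng <- max(1L, round(n_guilds * 3 / 8))
  if (np + ng > n_guilds) ng <- n_guilds - np
  npr <- n_guilds - np - ng
  level <- c(rep("producer", np), rep("grazer", ng), rep("predator", npr))
  guild <- paste0(c(P = "P", grazer = "G", predator = "Z")[
    match(level, c("producer", "grazer", "predator"))],
    unlist(lapply(c(np, ng, npr), seq_len))[seq_len(n_guilds)])
  list(guild = guild, level = level)
}

# Built-in predator-prey web: grazers eat producers, predators eat
# grazers, assigned round-robin with two prey each where available.
default_coupling <- function(roles, growth_rates) {
  n <- length(roles$guild)
  C <- matrix(0, n, n, dimnames = list(roles$guild, roles$guild))
  diag(C) <- -growth_rates
  prod_idx <- which(roles$level == "producer")
  gr_idx <- which(roles$level == "grazer")
  pred_idx <- which(roles$level == "predator")
  link <- function(prey, pred) {
    C[pred, prey] <<- 0.1    # bottom-up: prey abundance boosts predator
    C[prey, pred] <<- -0.25  # top-down: predator suppresses prey
  }
  for (k in seq_along(gr_idx)) {
    prey <- prod_idx[1 + (k - 1) %% length(prod_idx)]
    link(prey, gr_idx[k])
    if (length(prod_idx) > 1) {
      prey2 <- prod_idx[1 + k %% length(prod_idx)]
      if (prey2 != prey) link(prey2, gr_idx[k])
    }
  }
  for (k in seq_along(pred_idx)) {
    prey <- gr_idx[1 + (k - 1) %% length(gr_idx)]
    link(prey, pred_idx[k])
  }
  C
}

#' Minimal two-species fixture with unidirectional forcing
#'
#' A two-guild configuration where guild `P1` drives guild `G1` but not
#' vice versa, used to verify that cross-mapping detects the direction of
#' causation.  Driver sensitivities are zeroed so the only coupling is
#' the biotic one.
#'
#' @param seed integer seed.
#' @param strength signed effect of `P1` on `G1`'s growth (default -0.35).
#' @param ... further overrides passed to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
two_species_config <- function(seed = 1L, strength = -0.35, ...) {
  cfg <- synthetic_config(n_guilds = 2L, seed = seed,
                          driver_effects = matrix(0, 2, 2), ...)
  C <- matrix(0, 2, 2, dimnames = list(cfg$guilds, cfg$guilds))
  diag(C) <- -cfg$growth_rates
  C[2, 1] <- strength            # P1 -> G1 only
  cfg$coupling <- C
  cfg
}

#' Simulate environmental driver series
#'
#' Temperature is an annual sinusoid around `temp_mean` plus a linear
#' warming ramp (`temp_trend` degC per decade) and an AR(1) anomaly.
#' Phosphate is an annual sinusoid around an exponentially declining
#' baseline (`phosphate_decline` fraction per decade) times a lognormal
#' AR(1) anomaly, optionally modulated by the temperature anomaly
#' (`temp_phos_coupling`), mimicking reduced mixing in warm years.
#' Month 1 is January; the ramp and decline are zero at month 1.
#'
#' @param config a [synthetic_config()].
#' @return data frame `month`, `temperature`, `phosphate` with
#'   `n_months` rows.  Identical seeds give identical output.
#' @export
generate_drivers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_months
  t0 <- seq_len(n) - 1  # months since start
  season <- sin(2 * pi * (t0 - 3) / 12)  # peaks in July for January start
  with_seed(config$seed, {
    temp_anom <- ar1_noise(n, config$temp_noise_sd, 0.6)
    phos_anom <- ar1_noise(n, config$phos_noise_sd, 0.5)
    temperature <- config$temp_mean +
      config$temp_seasonal_amp * season +
      config$temp_trend * t0 / 120 +
      temp_anom
    base <- config$phos_baseline * (1 - config$phosphate_decline)^(t0 / 120)
    phosphate <- base * (1 + config$phos_seasonal_amp * season) *
      exp(phos_anom + config$temp_phos_coupling * temp_anom)
    data.frame(month = seq_len(n), temperature = temperature,
               phosphate = phosphate)
  })
}

# AR(1) innovations with stationary sd `sd_target`.
ar1_noise <- function(n, sd_target, rho) {
  if (sd_target == 0) return(numeric(n))
  e <- rnorm(n, 0, sd_target * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_target)
  for (t in 2:n) x[t] <- rho * x[t - 1] + e[t]
  x
}

#' Simulate guild abundances with known directed topology
#'
#' Discrete-time multispecies Ricker map with multiplicative 12-month
#' forcing and driver modulation:
#' `N[t+1, i] = N[t, i] * exp(r_i * s_i(t) + sum_j C[i, j] N[t, j] +
#' beta_i . env(t) + eps)`, where `s_i(t) = 1 + A_i sin(2 pi (t -
#' phase_i - 3) / 12)` and `env(t)` holds the standardized temperature
#' and phosphate series.  Observation noise is lognormal multiplicative.
#' Abundances are non-negative by construction.
#'
#' @param config a [synthetic_config()].
#' @param drivers output of [generate_drivers()] (same config).
#' @return list with `table` (data frame: `month` + one column per
#'   guild) and `truth`, a list with `directed_edges` (data frame
#'   `driver`, `driven`, `sign` for every nonzero off-diagonal coupling)
#'   and `driver_edges` (`driver`, `guild`, `sign` for nonzero driver
#'   sensitivities).
#' @export
generate_foodweb <- function(config, drivers = generate_drivers(config)) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_months
  if (nrow(drivers) != n) stop("drivers length (", nrow(drivers),
                               ") != n_months (", n, ")")
  g <- config$n_guilds
  C <- config$coupling
  if (!all(dim(C) == g)) stop("coupling matrix has wrong shape")
  zT <- as.numeric(scale(drivers$temperature))
  zP <- as.numeric(scale(drivers$phosphate))
  t0 <- seq_len(n) - 1
  seas <- sapply(seq_len(g), function(i) {
    1 + config$seasonal_amplitude[i] *
      sin(2 * pi * (t0 - 3 - config$seasonal_phase[i]) / 12)
  })  # n x g
  bT <- config$driver_effects[, 1]
  bP <- config$driver_effects[, 2]
  r <- config$growth_rates

  with_seed(config$seed + 1L, {
    N <- matrix(0, n, g, dimnames = list(NULL, config$guilds))
    N[1, ] <- runif(g, 0.5, 1.5)
    eps <- matrix(rnorm(n * g, 0, config$process_noise_sd), n, g)
    for (t in 1:(n - 1)) {
      expo <- r * seas[t, ] + as.numeric(C %*% N[t, ]) +
        bT * zT[t] + bP * zP[t] + eps[t, ]
      expo <- pmin(expo, 10)  # guard against numeric blow-up
      N[t + 1, ] <- N[t, ] * exp(expo)
    }
    obs <- N * exp(matrix(rnorm(n * g, 0, config$obs_noise_sd), n, g))
    if (config$missing_frac > 0) {
      drop <- matrix(runif(n * g) < config$missing_frac, n, g)
      obs[drop] <- NA_real_
    }
    table <- data.frame(month = seq_len(n), obs, check.names = FALSE)
    off <- which(C != 0 & row(C) != col(C), arr.ind = TRUE)
    directed_edges <- data.frame(
      driver = config$guilds[off[, "col"]],
      driven = config$guilds[off[, "row"]],
      sign = sign(C[off]))
    de <- which(config$driver_effects != 0, arr.ind = TRUE)
    driver_edges <- data.frame(
      driver = c("temperature", "phosphate")[de[, "col"]],
      guild = config$guilds[de[, "row"]],
      sign = sign(config$driver_effects[de]))
    list(table = table,
         truth = list(directed_edges = directed_edges,
                      driver_edges = driver_edges))
  })
}

#' Candidate-link template for the synthetic web
#'
#' Builds the typed guild graph that plays the role of the conceptual
#' network for synthetic data: all ordered pairs between guilds are
#' candidate links.  Adjacent trophic levels are `trophic`
#' (`bottom_up` going up, `top_down` going down), within-level pairs are
#' `non_trophic` (`lateral`), and producer-predator pairs (skipping a
#' level) are `hybrid`.
#'
#' @param config a [synthetic_config()].
#' @return a [guild_graph()].
#' @export
synthetic_guild_graph <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lv <- match(config$levels, c("producer", "grazer", "predator"))
  nodes <- data.frame(guild = config$guilds,
                      trophic_level = config$levels,
                      class = config$levels)
  pairs <- expand.grid(i = seq_len(config$n_guilds),
                       j = seq_len(config$n_guilds))
  pairs <- pairs[pairs$i != pairs$j, ]
  dl <- lv[pairs$j] - lv[pairs$i]   # driven level minus driver level
  type <- ifelse(dl == 0, "non_trophic", ifelse(abs(dl) == 1, "trophic", "hybrid"))
  dir <- ifelse(dl == 0, "lateral", ifelse(dl > 0, "bottom_up", "top_down"))
  links <- data.frame(driver = config$guilds[pairs$i],
                      driven = config$guilds[pairs$j],
                      interaction_type = type,
                      trophic_direction = dir)
  guild_graph(nodes, links)
}
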