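# Convergent cross-mapping network stage: convergence screening,
# moving-window local skill, seasonal-surrogate significance/strength,
# and the driver-effect / feedback analogues.

#' Library-size convergence test for a cross-mapped pair
#'
#' Tests whether cross-map skill for the direction driver -> affected
#' increases with library size, the hallmark of a causal imprint.  Skill
#' is computed for `n_subsets` contiguous random library segments at
#' each of two library fractions, and a paired one-sided t-test asks
#' whether the large-library skills exceed the small-library ones.
#'
#' @param affected,driver numeric series of equal length.
#' @param E embedding dimension for the affected variable.
#' @param n_subsets number of random segments per fraction (default 100).
#' @param frac_small,frac_large library fractions (defaults 0.2, 0.5).
#' @param seed integer seed for the segment draws.
#' @param tau lag (default 1).
#' @param tp estimation horizon (default 0, the convergence-stage
#'   convention).
#' @param alpha test level (default 0.05, i.e. the 95% level).
#' @return list with `convergent` (logical), `p_value`, `rho_small`,
#'   `rho_large` (the per-subset skills).
#' @export
convergence_test <- function(affected, driver, E, n_subsets = 100L,
                             frac_small = 0.2, frac_large = 0.5,
                             seed = 1L, tau = 1L, tp = 0L, alpha = 0.05) {
  if (!(frac_small < frac_large)) stop("invalid config: frac_small must be < frac_large")
  if (n_subsets < 2) stop("invalid config: n_subsets must be >= 2")
  az <- zscore(affected)
  dz <- zscore(driver)
  emb <- embed_series(az, E, tau)
  y <- shift_series(dz, tp)
  usable <- emb$valid[is.finite(y[emb$valid])]
  nv <- length(usable)
  k <- E + 1L
  len_s <- floor(frac_small * nv)
  len_l <- floor(frac_large * nv)
  if (len_s < k + 2) stop("insufficient data: small-fraction library has ",
                          len_s, " rows")
  rhos <- with_seed(seed, {
    start_s <- sample.int(nv - len_s + 1L, n_subsets, replace = TRUE)
    start_l <- sample.int(nv - len_l + 1L, n_subsets, replace = TRUE)
    subset_rho <- function(start, len) {
      lib <- usable[start:(start + len - 1L)]
      fit <- nn_predict(emb, y, lib, usable, k, 0L)
      obs <- y[usable]
      ok <- is.finite(fit$predictions) & is.finite(obs)
      if (sum(ok) < 3) return(NA_real_)
      stats::cor(fit$predictions[ok], obs[ok])
    }
    list(small = vapply(seq_len(n_subsets), function(i) subset_rho(start_s[i], len_s), numeric(1)),
         large = vapply(seq_len(n_subsets), function(i) subset_rho(start_l[i], len_l), numeric(1)))
  })
  ok <- is.finite(rhos$small) & is.finite(rhos$large)
  p <- tryCatch(
    stats::t.test(rhos$large[ok], rhos$small[ok], paired = TRUE,
                  alternative = "greater")$p.value,
    error = function(e) NA_real_)
  list(convergent = isTRUE(p < alpha), p_value = p,
       rho_small = rhos$small, rho_large = rhos$large)
}

#' Seasonal surrogate ensemble
#'
#' Generates null series that preserve the mean seasonal cycle (monthly
#' climatology) of `x` exactly while destroying interannual and causal
#' structure: within each calendar month, the observed anomalies are
#' permuted across years.  Missing values stay missing.
#'
#' @param x numeric monthly series (month 1 is calendar month 1); length
#'   >= 24.
#' @param n ensemble size.
#' @param seed integer seed.
#' @param method `"shuffle"` (default) permutes within-calendar-month
#'   anomalies across years — the least-assumption null, conserving the
#'   within-month value sets exactly but destroying anomaly persistence.
#'   `"phase"` phase-randomizes the anomaly series in the Fourier domain
#'   (preserving its power spectrum, hence autocorrelation) before adding
#'   the climatology back; it requires a gap-free series.
#' @return `length(x) x n` matrix, one surrogate per column.
#' @export
seasonal_surrogates <- function(x, n, seed = 1L,
                                method = c("shuffle", "phase")) {
  method <- match.arg(method)
  nt <- length(x)
  if (nt < 24) stop("series too short for seasonal surrogates (need >= 24 months)")
  month <- ((seq_len(nt) - 1L) %% 12L) + 1L
  per_month_n <- tapply(is.finite(x), month, sum)
  if (any(per_month_n < 2))
    stop("seasonal surrogates need >= 2 observed years for every calendar month")
  if (method == "phase") {
    if (anyNA(x) || any(!is.finite(x)))
      stop("phase-randomized surrogates require a gap-free series")
    clim <- ave(x, month)
    anom <- x - clim
    sp <- stats::fft(anom)
    even <- nt %% 2 == 0
    half <- if (even) seq2(2, nt / 2) else seq2(2, (nt + 1) / 2)
    return(with_seed(seed, {
      out <- matrix(NA_real_, nt, n)
      for (s in seq_len(n)) {
        sps <- sp
        if (length(half)) {
          ph <- stats::runif(length(half), 0, 2 * pi)
          sps[half] <- Mod(sp[half]) * exp(1i * ph)
          # mirror to keep the inverse transform real
          sps[nt + 2 - half] <- Conj(sps[half])
        }
        if (even) sps[nt / 2 + 1] <- sp[nt / 2 + 1] * sample(c(-1, 1), 1)
        out[, s] <- clim + Re(stats::fft(sps, inverse = TRUE)) / nt
      }
      out
    }))
  }
  # Permuting anomalies within a calendar month is identical to permuting
  # the observed values themselves (the climatology is constant within the
  # month), and doing the latter preserves the values bit-for-bit.
  with_seed(seed, {
    out <- matrix(NA_real_, nt, n)
    idx_by_month <- split(seq_len(nt), month)
    for (s in seq_len(n)) {
      xs <- x
      for (m in 1:12) {
        pos <- idx_by_month[[m]]
        obs <- pos[is.finite(x[pos])]
        xs[obs] <- x[sample(obs)]
      }
      out[, s] <- xs
    }
    out
  })
}

# Moving-window Pearson skill of an aligned obs/prediction pair.
# Windows of `window` months slide one month at a time over the span of
# predicted target times; each is stamped at its centre month.
local_skill_series <- function(observed, predictions, window,
                               min_pairs = 3L) {
  ok <- is.finite(observed) & is.finite(predictions)
  if (!any(ok)) stop("no complete observation/prediction pairs")
  t1 <- min(which(ok))
  t2 <- max(which(ok))
  if (t2 - t1 + 1L < window) stop("window (", window,
                                  ") exceeds prediction span (", t2 - t1 + 1L, ")")
  rng <- t1:t2
  r <- rolling_cor(observed[rng], predictions[rng], window, min_pairs)
  starts <- t1 + seq_along(r) - 1L
  data.frame(window_centre = window_centre(starts, window), local_rho = r)
}

#' Moving-window cross-map skill for one directed pair
#'
#' Runs a single full-library cross-map (tp = -1 by convention for the
#' final network stage) and computes the local Pearson skill between
#' observed and cross-map-estimated driver values within moving windows
#' (default 60 months, sliding 1 month), stamped at the window centre.
#'
#' @param affected,driver numeric series.
#' @param E embedding dimension for the affected variable.
#' @param window window length in months (default 60).
#' @param tau,tp embedding lag and horizon (defaults 1, -1).
#' @param exclusion_radius temporal exclusion (default 0).
#' @return list with `local` (data frame `window_centre`, `local_rho`),
#'   `whole_rho`, and `cm`, the full cross-map fit (with neighbour
#'   structure, used by the surrogate stage).
#' @export
local_rho <- function(affected, driver, E, window = 60L, tau = 1L,
                      tp = -1L, exclusion_radius = 0L) {
  cm <- cross_map(affected, driver, E, tau = tau, tp = tp,
                  exclusion_radius = exclusion_radius,
                  keep_neighbours = TRUE)
  local <- local_skill_series(cm$observed, cm$predictions, window)
  list(local = local, whole_rho = cm$rho, cm = cm)
}

# Re-predict the cross-map with a surrogate driver series (the affected
# manifold and neighbour weights are unchanged; only the estimated values
# change) and return its local-skill series on the same window grid.
surrogate_local_rho <- function(cm, surrogate, window) {
  nb <- cm$neighbours
  n <- length(cm$observed)
  y <- shift_series(surrogate, nb$tp)
  preds <- predict_from_neighbours(nb, y)
  predictions <- observed <- rep(NA_real_, n)
  tgt <- nb$rows + nb$tp
  keep <- tgt >= 1 & tgt <= n
  predictions[tgt[keep]] <- preds[keep]
  observed[tgt[keep]] <- y[nb$rows[keep]]
  # restrict to the original span so window grids align
  ok0 <- is.finite(cm$observed) & is.finite(cm$predictions)
  t1 <- min(which(ok0)); t2 <- max(which(ok0))
  rng <- t1:t2
  rolling_cor(observed[rng], predictions[rng], window)
}

#' Seasonal-surrogate significance and corrected strength
#'
#' Per window, a link is significant when the original local skill beats
#' at least 95% of the surrogate ensemble (strict inequality; ties count
#' against significance).  Where significant, the interaction strength is
#' the seasonally corrected skill `local_rho - mean(surrogate rho)`,
#' floored at zero; elsewhere it is zero.  Windows with missing original
#' skill are flagged `skipped` and carry `NA` strength.
#'
#' @param local data frame `window_centre`, `local_rho`.
#' @param surrogate_rhos matrix, one column per surrogate, rows aligned
#'   with `local`.
#' @param level required beat fraction (default 0.95).
#' @return data frame `window_centre`, `local_rho`, `strength`,
#'   `significant`, `skipped`.
#' @export
significance_and_strength <- function(local, surrogate_rhos, level = 0.95) {
  surrogate_rhos <- as.matrix(surrogate_rhos)
  n_surr <- ncol(surrogate_rhos)
  if (n_surr < 20) stop("surrogate ensemble too small (need >= 20)")
  if (nrow(surrogate_rhos) != nrow(local))
    stop("surrogate ensemble misaligned with window grid")
  need <- ceiling(level * n_surr)
  orig <- local$local_rho
  beats <- rowSums(orig > surrogate_rhos, na.rm = TRUE)
  sig <- is.finite(orig) & beats >= need
  surr_mean <- rowMeans(surrogate_rhos, na.rm = TRUE)
  strength <- ifelse(sig, pmax(orig - surr_mean, 0), 0)
  skipped <- !is.finite(orig)
  strength[skipped] <- NA_real_
  sig[skipped] <- FALSE
  data.frame(window_centre = local$window_centre, local_rho = orig,
             strength = strength, significant = sig, skipped = skipped)
}

# Full per-pair analysis: E selection on the affected variable,
# convergence screen, full-library local skill, surrogate correction.
ccm_link <- function(affected, driver, config, seed,
                     E = NULL, conv = NULL) {
  if (is.null(E)) E <- as.integer(select_E(affected, config$E_range,
                                           config$tau, tp = 1L))
  if (is.null(conv)) {
    conv <- convergence_test(affected, driver, E,
                             n_subsets = config$n_convergence_subsets,
                             frac_small = config$lib_fractions[1],
                             frac_large = config$lib_fractions[2],
                             seed = seed, tau = config$tau, tp = 0L)
  }
  lr <- local_rho(affected, driver, E, window = config$window,
                  tau = config$tau, tp = -1L,
                  exclusion_radius = config$ccm_exclusion_radius)
  if (conv$convergent) {
    surr <- seasonal_surrogates(zscore(driver), config$n_surrogates,
                                seed = (seed + 1L) %% 2147483647L)
    surr_rhos <- vapply(seq_len(ncol(surr)), function(s) {
      surrogate_local_rho(lr$cm, surr[, s], config$window)
    }, numeric(nrow(lr$local)))
    link <- significance_and_strength(lr$local, surr_rhos)
  } else {
    link <- data.frame(window_centre = lr$local$window_centre,
                       local_rho = lr$local$local_rho,
                       strength = 0, significant = FALSE,
                       skipped = !is.finite(lr$local$local_rho))
    link$strength[link$skipped] <- NA_real_
  }
  list(link = link, E = E, convergent = conv$convergent,
       conv_p = conv$p_value, whole_rho = lr$whole_rho)
}

#' Build the time-varying causal network for a guild table
#'
#' Runs the full per-pair pipeline over every candidate directed link of
#' the guild graph: embedding-dimension selection on the driven (affected)
#' variable, library-convergence screening, full-library moving-window
#' cross-map skill, and seasonal-surrogate significance and strength.
#' Non-convergent pairs carry an all-zero strength series flagged
#' non-convergent.  Per-pair random draws are seeded from the master seed
#' and a stable hash of the ordered pair, so results for one pair do not
#' depend on which other pairs are analysed.
#'
#' @param table data frame with a `month` column and one numeric column
#'   per guild.
#' @param graph a [guild_graph()] whose guilds all appear in `table`.
#' @param config a [run_config()].
#' @return object of class `ccm_network`: list with `links` (long data
#'   frame `driver`, `driven`, `window_centre`, `local_rho`, `strength`,
#'   `significant`, `skipped`), `meta` (per-pair `E`, `convergent`,
#'   `conv_p`, `whole_rho`), `graph`, and `config`.
#' @export
build_network <- function(table, graph, config = run_config()) {
  missing_cols <- setdiff(graph$nodes$guild, names(table))
  if (length(missing_cols))
    stop("schema error: guild column(s) missing from table: ",
         paste(missing_cols, collapse = ", "))
  links <- graph$links
  E_cache <- list()
  out_links <- vector("list", nrow(links))
  meta <- vector("list", nrow(links))
  for (i in seq_len(nrow(links))) {
    drv <- links$driver[i]
    dvn <- links$driven[i]
    affected <- table[[dvn]]
    driver <- table[[drv]]
    if (is.null(E_cache[[dvn]]))
      E_cache[[dvn]] <- as.integer(select_E(affected, config$E_range,
                                            config$tau, tp = 1L))
    seed <- pair_seed(config$master_seed, drv, dvn)
    fit <- ccm_link(affected, driver, config, seed, E = E_cache[[dvn]])
    out_links[[i]] <- cbind(driver = drv, driven = dvn, fit$link,
                            stringsAsFactors = FALSE)
    meta[[i]] <- data.frame(driver = drv, driven = dvn, E = fit$E,
                            convergent = fit$convergent,
                            conv_p = fit$conv_p,
                            whole_rho = fit$whole_rho)
  }
  empty_links <- data.frame(driver = character(), driven = character(),
                            window_centre = integer(),
                            local_rho = numeric(), strength = numeric(),
                            significant = logical(), skipped = logical())
  empty_meta <- data.frame(driver = character(), driven = character(),
                           E = integer(), convergent = logical(),
                           conv_p = numeric(), whole_rho = numeric())
  structure(list(links = do.call(rbind, out_links) %||% empty_links,
                 meta = do.call(rbind, meta) %||% empty_meta,
                 graph = graph, config = config),
            class = "ccm_network")
}

#' @export
print.ccm_network <- function(x, ...) {
  cat("ccm_network:", nrow(x$meta), "candidate links,",
      sum(x$meta$convergent), "convergent;",
      length(unique(x$links$window_centre)), "windows\n")
  invisible(x)
}

#' Environmental-driver effect on one guild
#'
#' Applies the cross-mapping machinery with an environmental variable
#' (temperature or phosphate) as the causal driver of a guild, and
#' summarises the effect as the mean strength over significant windows
#' multiplied by the prevalence of significance (fraction of windows
#' significant).
#'
#' @param guild_series numeric guild abundance series.
#' @param driver_series numeric environmental series.
#' @param config a [run_config()].
#' @param seed integer seed (default derived from the master seed).
#' @return list with `link` (the per-window data frame), `E`,
#'   `convergent`, and `effect`, the prevalence-weighted scalar.
#' @export
driver_effect <- function(guild_series, driver_series,
                          config = run_config(), seed = NULL) {
  if (is.null(seed)) seed <- pair_seed(config$master_seed, "env", "guild")
  fit <- ccm_link(guild_series, driver_series, config, seed)
  list(link = fit$link, E = fit$E, convergent = fit$convergent,
       effect = prevalence_weighted_strength(fit$link))
}

#' Causal feedback test between two environmental drivers
#'
#' Tests both causal directions between, e.g., water temperature and
#' phosphate.  A direction is significant only if (i) the library
#' convergence test passes and (ii) the whole-series cross-map skill
#' beats at least 95% of the seasonal-surrogate ensemble.  The effect
#' magnitude is the prevalence-weighted moving-window strength.
#'
#' @param a,b numeric series (e.g. temperature, phosphate).
#' @param config a [run_config()].
#' @param names_ab character(2), labels for the two series.
#' @return data frame with one row per direction: `driver`, `driven`,
#'   `convergent`, `surrogate_pass`, `significant`, `whole_rho`,
#'   `effect` (prevalence-weighted strength).
#' @export
feedback_test <- function(a, b, config = run_config(),
                          names_ab = c("a", "b")) {
  one_direction <- function(driver, affected, dn, an) {
    seed <- pair_seed(config$master_seed, dn, an)
    E <- as.integer(select_E(affected, config$E_range, config$tau, tp = 1L))
    conv <- convergence_test(affected, driver, E,
                             n_subsets = config$n_convergence_subsets,
                             frac_small = config$lib_fractions[1],
                             frac_large = config$lib_fractions[2],
                             seed = seed, tau = config$tau, tp = 0L)
    lr <- local_rho(affected, driver, E, window = config$window,
                    tau = config$tau, tp = -1L)
    surr <- seasonal_surrogates(zscore(driver), config$n_surrogates,
                                seed = (seed + 1L) %% 2147483647L)
    # whole-series surrogate skills
    surr_whole <- vapply(seq_len(ncol(surr)), function(s) {
      y <- shift_series(surr[, s], -1L)
      nb <- lr$cm$neighbours
      preds <- predict_from_neighbours(nb, y)
      obs <- y[nb$rows]
      ok <- is.finite(preds) & is.finite(obs)
      if (sum(ok) < 3) return(NA_real_)
      stats::cor(preds[ok], obs[ok])
    }, numeric(1))
    need <- ceiling(0.95 * config$n_surrogates)
    surrogate_pass <- sum(lr$whole_rho > surr_whole, na.rm = TRUE) >= need
    surr_rhos <- vapply(seq_len(ncol(surr)), function(s) {
      surrogate_local_rho(lr$cm, surr[, s], config$window)
    }, numeric(nrow(lr$local)))
    link <- significance_and_strength(lr$local, surr_rhos)
    data.frame(driver = dn, driven = an,
               convergent = conv$convergent,
               surrogate_pass = surrogate_pass,
               significant = conv$convergent && surrogate_pass,
               whole_rho = lr$whole_rho,
               effect = prevalence_weighted_strength(link))
  }
  rbind(one_direction(a, b, names_ab[1], names_ab[2]),
        one_direction(b, a, names_ab[2], names_ab[1]))
}
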