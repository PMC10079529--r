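# Multivariate S-map modelling of network properties over environmental
# gradients, with ensemble prediction on a temperature x phosphate grid.

#' Assemble an S-map scenario block
#'
#' Aligns one network-property series with smoothed environmental
#' predictors and lake morphometry.  Drivers are smoothed with a centred
#' moving window (default 60 months) to match the temporal scale of the
#' moving-window network properties, then sampled at the property's
#' window-centre months.  Rows with missing response are dropped.
#'
#' @param property data frame with `window_centre` and one value column
#'   (the first non-key column is used).
#' @param drivers data frame `month`, `temperature`, `phosphate`.
#' @param depth lake depth at the sampling site (m, constant).
#' @param volume lake volume (km^3, constant).
#' @param smooth smoothing window in months (default 60).
#' @return object of class `scenario_block`: list with `X` (predictor
#'   matrix: temperature, phosphate, depth, volume), `y`, `time`
#'   (window-centre months), `response` (column name).
#' @export
scenario_block <- function(property, drivers, depth, volume, smooth = 60L) {
  stopifnot("window_centre" %in% names(property),
            all(c("month", "temperature", "phosphate") %in% names(drivers)))
  value_col <- setdiff(names(property), "window_centre")[1]
  Ts <- smooth_window(drivers$temperature, smooth)
  Ps <- smooth_window(drivers$phosphate, smooth)
  idx <- match(property$window_centre, drivers$month)
  if (anyNA(idx)) stop("window centres outside driver series")
  y <- property[[value_col]]
  keep <- is.finite(y) & is.finite(Ts[idx]) & is.finite(Ps[idx])
  X <- cbind(temperature = Ts[idx][keep], phosphate = Ps[idx][keep],
             depth = rep(depth, sum(keep)), volume = rep(volume, sum(keep)))
  structure(list(X = X, y = y[keep],
                 time = property$window_centre[keep],
                 response = value_col, depth = depth, volume = volume),
            class = "scenario_block")
}

# Column standardization with the block's library statistics.
# Zero-variance columns (e.g. depth/volume in a single-lake block) are
# centred only, so they contribute nothing to distances or slopes.
block_scaling <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv,
       apply = function(M) sweep(sweep(M, 2, mu), 2, sdv, "/"))
}

#' Select the S-map state-dependence parameter
#'
#' Cross-validated skill (Pearson rho of leave-out predictions at tp = 0)
#' over a grid of theta values, with a temporal exclusion radius
#' (default 12 months) so the strong autocorrelation induced by
#' moving-window properties cannot leak into the library.  Ties go to
#' the smallest theta (theta = 0 is the global linear model).
#'
#' @param block a [scenario_block()].
#' @param theta_grid candidate values; default the standard 18-value
#'   grid from 0 to 8.
#' @param exclusion_radius months excluded around each library query
#'   (default 12).
#' @return the selected theta, with attribute `rho_profile`.
#' @export
fit_theta <- function(block, theta_grid = default_theta_grid(),
                      exclusion_radius = 12L) {
  if (!length(theta_grid)) stop("theta_grid is empty")
  if (nrow(block$X) < 20) stop("insufficient rows for theta selection (need >= 20)")
  theta_grid <- sort(unique(theta_grid))
  sc <- block_scaling(block$X)
  Xz <- sc$apply(block$X)
  rhos <- vapply(theta_grid, function(th) {
    fit <- smap_forecast(Xz, block$y, th, exclusion_radius,
                         lib_time = block$time)
    fit$rho
  }, numeric(1))
  if (all(!is.finite(rhos))) stop("no finite skill for any theta")
  best <- theta_grid[which.max(round(rhos, 10))]
  structure(best, rho_profile = stats::setNames(rhos, theta_grid))
}

#' @rdname fit_theta
#' @export
default_theta_grid <- function() {
  c(0, 1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03, 0.1, 0.3, 0.5, 0.75,
    1, 1.5, 2, 3, 4, 6, 8)
}

#' Ensemble S-map prediction over a temperature x phosphate grid
#'
#' Fits `n_models` S-map models on random half-libraries of the block
#' and evaluates each at every grid cell (query vector = temperature,
#' phosphate, with depth and volume held at the lake's values).  Grid
#' queries carry no time stamp, so no temporal exclusion applies to
#' them.  Returns the per-cell ensemble mean and standard deviation —
#' the uncertainty estimate.
#'
#' @param block a [scenario_block()].
#' @param grid_axes list with numeric vectors `temperature` and
#'   `phosphate` (see [make_grid_axes()]).
#' @param theta S-map weighting parameter (from [fit_theta()]).
#' @param n_models ensemble size (default 100).
#' @param subsample_frac fraction of rows per model (default 0.5).
#' @param seed integer seed.
#' @param contiguous if `TRUE`, subsets are contiguous time blocks
#'   instead of uniform row draws.
#' @return object of class `scenario_grid`: data frame `temperature`,
#'   `phosphate`, `mean`, `sd`, `n_ok` (models yielding a finite
#'   prediction), with the axes and call settings in attributes.
#' @export
ensemble_predict <- function(block, grid_axes, theta, n_models = 100L,
                             subsample_frac = 0.5, seed = 1L,
                             contiguous = FALSE) {
  if (n_models < 2) stop("n_models must be >= 2")
  if (!(subsample_frac > 0 && subsample_frac < 1))
    stop("subsample_frac must be in (0, 1)")
  n <- nrow(block$X)
  m <- max(4L, floor(subsample_frac * n))
  sc <- block_scaling(block$X)
  Xz <- sc$apply(block$X)
  cells <- expand.grid(temperature = grid_axes$temperature,
                       phosphate = grid_axes$phosphate,
                       KEEP.OUT.ATTRS = FALSE)
  Q <- cbind(temperature = cells$temperature, phosphate = cells$phosphate,
             depth = rep(block$depth, nrow(cells)),
             volume = rep(block$volume, nrow(cells)))
  Qz <- sc$apply(Q)
  preds <- with_seed(seed, {
    vapply(seq_len(n_models), function(i) {
      rows <- if (contiguous) {
        start <- sample.int(n - m + 1L, 1L)
        start:(start + m - 1L)
      } else sort(sample.int(n, m))
      fit <- smap_forecast(Xz[rows, , drop = FALSE], block$y[rows], theta,
                           exclusion_radius = 0L,
                           lib_time = block$time[rows],
                           queries = Qz)
      fit$predictions
    }, numeric(nrow(Qz)))
  })
  mu <- rowMeans(preds, na.rm = TRUE)
  sdv <- apply(preds, 1, function(v) stats::sd(v[is.finite(v)]))
  n_ok <- rowSums(is.finite(preds))
  mu[n_ok == 0] <- NA_real_
  out <- data.frame(temperature = cells$temperature,
                    phosphate = cells$phosphate,
                    mean = mu, sd = sdv, n_ok = n_ok)
  structure(out, class = c("scenario_grid", "data.frame"),
            axes = grid_axes, theta = theta, n_models = n_models,
            subsample_frac = subsample_frac, seed = seed,
            response = block$response)
}

#' Grid axes spanning the observed environmental ranges
#'
#' @param temperature,phosphate observed values (pool across lakes to
#'   span the cross-lake range).
#' @param resolution levels per axis (default 100, i.e. a 10,000-cell
#'   grid).
#' @return list with `temperature` and `phosphate` vectors.
#' @export
make_grid_axes <- function(temperature, phosphate, resolution = 100L) {
  list(temperature = seq(min(temperature, na.rm = TRUE),
                         max(temperature, na.rm = TRUE),
                         length.out = resolution),
       phosphate = seq(min(phosphate, na.rm = TRUE),
                       max(phosphate, na.rm = TRUE),
                       length.out = resolution))
}

#' Mask of grid cells inside the observed predictor ranges
#'
#' Marks cells whose temperature and phosphate both lie within the
#' central `band` (default 95%) marginal range of the observed
#' predictors, separating interpolation from extrapolation when
#' reporting scenario surfaces.
#'
#' @param block a [scenario_block()].
#' @param grid a [ensemble_predict()] result or any data frame with
#'   `temperature` and `phosphate` columns.
#' @param band central coverage in (0, 1]; `1` is the min-max box.
#' @return logical vector, one entry per grid row.
#' @export
observed_range_mask <- function(block, grid, band = 0.95) {
  if (!(band > 0 && band <= 1)) stop("band must be in (0, 1]")
  lims <- function(v) {
    if (band == 1) range(v) else
      stats::quantile(v, c((1 - band) / 2, 1 - (1 - band) / 2),
                      names = FALSE)
  }
  tl <- lims(block$X[, "temperature"])
  pl <- lims(block$X[, "phosphate"])
  grid$temperature >= tl[1] & grid$temperature <= tl[2] &
    grid$phosphate >= pl[1] & grid$phosphate <= pl[2]
}
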