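#' Time-delay embedding of a series
#'
#' Builds the lagged coordinate block used for state-space
#' reconstruction: row `t` holds `(x[t], x[t - tau], ...,
#' x[t - (E-1)*tau])`.  Rows whose coordinates reach before the start of
#' the series, or touch a missing value, are excluded from `valid`.
#'
#' @param x numeric series, evenly spaced; may contain `NA`.
#' @param E embedding dimension (>= 1).
#' @param tau lag in time steps (>= 1); monthly data uses 1.
#' @return list with `block` (`length(x) x E` matrix), `valid` (integer
#'   vector of fully observed rows), `E`, `tau`.
#' @export
embed_series <- function(x, E, tau = 1L) {
  n <- length(x)
  if (E < 1 || tau < 1) stop("E and tau must be >= 1")
  if (n < (E - 1) * tau + 2) stop("insufficient data: series length ", n,
                                  " too short for E=", E, ", tau=", tau)
  block <- matrix(NA_real_, n, E)
  for (j in seq_len(E)) {
    lag <- (j - 1L) * tau
    if (lag < n) block[(lag + 1L):n, j] <- x[seq_len(n - lag)]
  }
  valid <- which(rowSums(is.finite(block)) == E)
  list(block = block, valid = valid, E = E, tau = tau)
}

# Shift a series by tp: result[r] = x[r + tp] (NA outside range).
shift_series <- function(x, tp) {
  n <- length(x)
  out <- rep(NA_real_, n)
  src <- seq_len(n) + tp
  ok <- src >= 1 & src <= n
  out[ok] <- x[src[ok]]
  out
}

# Shared nearest-neighbour prediction: given an embedding, target values
# aligned to embedding rows (y[r] is what a prediction made at row r
# estimates), library and prediction row sets, return per-row predictions.
# Returns neighbour structure so alternative target series (surrogates)
# can be re-predicted without repeating the neighbour search.
nn_predict <- function(emb, y, lib, pred, num_neighbors, exclusion_radius = 0L) {
  lib <- lib[is.finite(y[lib])]
  if (length(lib) < num_neighbors + 1)
    stop("insufficient library: ", length(lib), " rows for ",
         num_neighbors, " neighbours")
  nb <- simplex_neighbours_cpp(emb$block, as.integer(lib), as.integer(pred),
                               as.integer(num_neighbors),
                               as.integer(exclusion_radius))
  pred_vals <- predict_from_neighbours(nb, y)
  list(ind = nb$ind, w = nb$w, rows = pred, predictions = pred_vals)
}

# Weighted average of y over stored neighbours; rows with no neighbours
# give NA.  Used both for original and surrogate target series.
predict_from_neighbours <- function(nb, y) {
  ind <- nb$ind
  w <- nb$w
  yv <- matrix(y[ind], nrow(ind), ncol(ind))
  num <- rowSums(w * yv)
  den <- rowSums(w)
  out <- num / den
  out[!is.finite(out)] <- NA_real_
  out
}

#' Simplex-projection forecast with leave-one-out cross-validation
#'
#' Nearest-neighbour forecasting in the reconstructed state space: each
#' point is predicted from its `num_neighbors` (default `E + 1`) nearest
#' library points, weighted `exp(-d_i / d_1)`, with the point itself
#' (and any point within `exclusion_radius` time steps) excluded.
#'
#' @param x numeric series.
#' @param E embedding dimension.
#' @param tau lag (default 1).
#' @param tp prediction horizon in time steps (default 1).
#' @param num_neighbors neighbours per prediction (default `E + 1`).
#' @param exclusion_radius temporal exclusion (Theiler window), default 0
#'   (leave-one-out only).
#' @return list with `predictions` and `observed` (aligned to target
#'   times, length `length(x)`), `rho` (Pearson skill), `n_pred`, and the
#'   call parameters.
#' @export
simplex_forecast <- function(x, E, tau = 1L, tp = 1L,
                             num_neighbors = E + 1L,
                             exclusion_radius = 0L) {
  if (num_neighbors < 1) stop("num_neighbors must be >= 1")
  emb <- embed_series(x, E, tau)
  y <- shift_series(x, tp)
  lib <- emb$valid
  pred <- emb$valid[is.finite(y[emb$valid])]
  if (length(pred) <= num_neighbors + 1)
    stop("insufficient data: only ", length(pred), " valid rows")
  fit <- nn_predict(emb, y, lib, pred, num_neighbors, exclusion_radius)
  n <- length(x)
  predictions <- observed <- rep(NA_real_, n)
  tgt <- pred + tp
  keep <- tgt >= 1 & tgt <= n
  predictions[tgt[keep]] <- fit$predictions[keep]
  observed[tgt[keep]] <- y[pred[keep]]
  ok <- is.finite(predictions) & is.finite(observed)
  rho <- if (sum(ok) >= 3) stats::cor(predictions[ok], observed[ok]) else NA_real_
  list(predictions = predictions, observed = observed, rho = rho,
       n_pred = sum(ok), E = E, tau = tau, tp = tp,
       num_neighbors = num_neighbors)
}

#' Select the embedding dimension maximizing forecast skill
#'
#' Runs leave-one-out simplex projection over a range of embedding
#' dimensions and returns the one with the highest forecast skill rho
#' (ties resolved toward the smallest dimension).
#'
#' @param x numeric series.
#' @param E_range candidate dimensions (default `2:15`).
#' @param tau lag (default 1).
#' @param tp prediction horizon used for the skill profile (default 1).
#' @return integer, the selected `E`, with attribute `rho_profile`.
#' @export
select_E <- function(x, E_range = 2:15, tau = 1L, tp = 1L) {
  if (!length(E_range)) stop("E_range is empty")
  E_range <- sort(unique(as.integer(E_range)))
  rhos <- vapply(E_range, function(E) {
    simplex_forecast(x, E, tau = tau, tp = tp)$rho
  }, numeric(1))
  if (all(!is.finite(rhos))) stop("no finite skill for any E")
  best <- E_range[which.max(round(rhos, 10))]
  structure(best, rho_profile = stats::setNames(rhos, E_range))
}

#' Cross-map one variable from another's reconstructed state space
#'
#' Measures how much information about `driver` is imprinted in
#' `affected` (the causal direction driver -> affected): the affected
#' series is embedded and its simplex neighbours estimate the driver's
#' values at horizon `tp`.  Both series are standardized internally, so
#' skill is invariant to affine rescaling.
#'
#' @param affected numeric series whose attractor is used (the putatively
#'   affected variable).
#' @param driver numeric series to be estimated.
#' @param E embedding dimension for `affected` (from [select_E()]).
#' @param tau lag (default 1).
#' @param tp horizon at which the driver is estimated: 0 for
#'   convergence-test CCM, -1 for the final full-library cross-map.
#' @param lib optional vector of time indices allowed as library rows
#'   (contiguous subsets implement the convergence test).
#' @param num_neighbors default `E + 1`.
#' @param exclusion_radius temporal exclusion, default 0.
#' @param keep_neighbours if `TRUE`, the neighbour index/weight matrices
#'   are returned so surrogate driver series can be re-predicted cheaply.
#' @return list with `rho`, `n_pred`, `time` (target months),
#'   `observed`, `predictions` (length of the input series, aligned to
#'   target months), and optionally `neighbours`.
#' @export
cross_map <- function(affected, driver, E, tau = 1L, tp = 0L, lib = NULL,
                      num_neighbors = E + 1L, exclusion_radius = 0L,
                      keep_neighbours = FALSE) {
  n <- length(affected)
  if (length(driver) != n) stop("series lengths differ")
  az <- zscore(affected)
  dz <- zscore(driver)
  emb <- embed_series(az, E, tau)
  y <- shift_series(dz, tp)
  lib_rows <- emb$valid
  if (!is.null(lib)) lib_rows <- intersect(lib_rows, as.integer(lib))
  lib_rows <- lib_rows[is.finite(y[lib_rows])]
  if (length(lib_rows) < E + 2)
    stop("insufficient library: ", length(lib_rows), " rows (need ", E + 2, ")")
  pred <- emb$valid[is.finite(y[emb$valid])]
  fit <- nn_predict(emb, y, lib_rows, pred, num_neighbors, exclusion_radius)
  predictions <- observed <- rep(NA_real_, n)
  tgt <- pred + tp
  keep <- tgt >= 1 & tgt <= n
  predictions[tgt[keep]] <- fit$predictions[keep]
  observed[tgt[keep]] <- y[pred[keep]]
  ok <- is.finite(predictions) & is.finite(observed)
  rho <- if (sum(ok) >= 3) stats::cor(predictions[ok], observed[ok]) else NA_real_
  out <- list(rho = rho, n_pred = sum(ok), time = which(ok),
              observed = observed, predictions = predictions,
              E = E, tau = tau, tp = tp)
  if (keep_neighbours) {
    out$neighbours <- list(ind = fit$ind, w = fit$w, rows = pred, tp = tp)
    out$driver_z <- dz
  }
  out
}

#' S-map: locally weighted linear regression in predictor space
#'
#' For each query point, library rows are weighted
#' `exp(-theta * d / dbar)` (with `dbar` the mean distance to the query)
#' and a weighted linear regression with intercept is solved by SVD.
#' `theta = 0` reduces to a single global linear model.  Queries default
#' to the library rows themselves with leave-one-out via the exclusion
#' radius; arbitrary query vectors (e.g. scenario grid points, which
#' carry no time stamp) are supported.
#'
#' @param X numeric matrix of predictors (library rows).
#' @param y numeric response, `nrow(X)` values.
#' @param theta state-dependence weighting (>= 0).
#' @param exclusion_radius temporal exclusion for library queries.
#' @param lib_time time stamps of the library rows (default row order).
#' @param queries optional matrix of query vectors (default `X`).
#' @param query_time time stamps for queries (`NA` entries disable
#'   temporal exclusion for that query; default: `lib_time` when queries
#'   are the library, otherwise all `NA`).
#' @return list with `predictions`, `coefficients` (one row per query:
#'   intercept then one slope per predictor column), `ok` (logical,
#'   `FALSE` where the weighted design was degenerate), and `rho`
#'   (skill against `y` when queries are the library rows).
#' @export
smap_forecast <- function(X, y, theta, exclusion_radius = 0L,
                          lib_time = NULL, queries = NULL,
                          query_time = NULL) {
  X <- as.matrix(X)
  if (theta < 0) stop("theta must be >= 0")
  keep <- is.finite(y) & rowSums(!is.finite(X)) == 0
  Xl <- X[keep, , drop = FALSE]
  yl <- y[keep]
  lt <- if (is.null(lib_time)) seq_along(y) else lib_time
  lt <- lt[keep]
  self_query <- is.null(queries)
  if (self_query) {
    queries <- Xl
    query_time <- lt
  }
  queries <- as.matrix(queries)
  if (is.null(query_time)) query_time <- rep(NA_integer_, nrow(queries))
  qt <- ifelse(is.na(query_time), -1L, as.integer(query_time))
  res <- smap_predict_cpp(Xl, yl, as.integer(lt), queries, qt,
                          theta, as.integer(exclusion_radius))
  if (!any(res$ok)) stop("degenerate weighted design for every query")
  rho <- NA_real_
  if (self_query) {
    ok <- res$ok & is.finite(res$pred)
    if (sum(ok) >= 3) rho <- stats::cor(res$pred[ok], yl[ok])
  }
  colnames(res$coef) <- c("(Intercept)",
                          colnames(X) %||% paste0("x", seq_len(ncol(X))))
  list(predictions = as.numeric(res$pred), coefficients = res$coef,
       ok = as.logical(res$ok), rho = rho, theta = theta)
}
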