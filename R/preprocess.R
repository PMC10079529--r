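#' Winsorize a series at an upper (and optionally lower) quantile
#'
#' Replaces values lying above the `quantile` sample quantile by the largest
#' observed value at or below that quantile, damping the influence of large
#' outliers (for plankton counts, typically transcription errors) without
#' deleting data.  The quantile uses the linear-interpolation convention
#' (`type = 7`), recorded in the result's attributes.  Missing values pass
#' through untouched.
#'
#' @param x numeric vector, may contain `NA`.
#' @param quantile upper cut fraction in (0.5, 1); default 0.99.
#' @param two_sided if `TRUE`, the lower tail is treated symmetrically at
#'   `1 - quantile`.  Default `FALSE` (upper tail only).
#' @return numeric vector of the same length, with attributes
#'   `winsor_upper` (and `winsor_lower` when two-sided) and
#'   `quantile_type`.
#' @export
winsorize <- function(x, quantile = 0.99, two_sided = FALSE) {
  if (!(quantile > 0.5 && quantile < 1)) stop("quantile must be in (0.5, 1)")
  obs <- x[is.finite(x)]
  if (length(obs) == 0) stop("winsorize: series has no non-missing values")
  qu <- stats::quantile(obs, quantile, type = 7, names = FALSE)
  cap_hi <- max(obs[obs <= qu])
  out <- x
  out[is.finite(out) & out > qu] <- cap_hi
  attr(out, "winsor_upper") <- cap_hi
  if (two_sided) {
    ql <- stats::quantile(obs, 1 - quantile, type = 7, names = FALSE)
    cap_lo <- min(obs[obs >= ql])
    out[is.finite(out) & out < ql] <- cap_lo
    attr(out, "winsor_lower") <- cap_lo
  }
  attr(out, "quantile_type") <- 7L
  out
}

#' Standardize a series to zero mean and unit variance
#'
#' Non-missing values are centred and scaled by the sample standard
#' deviation (n - 1 denominator); missing values stay missing.  Required
#' before any distance-based step so that variables measured on different
#' scales (abundances, temperature, nutrients) are comparable.
#'
#' @param x numeric vector with at least two distinct non-missing values.
#' @return numeric vector of the same length.
#' @export
zscore <- function(x) {
  obs <- x[is.finite(x)]
  if (length(unique(obs)) < 2) stop("zscore: series is constant or empty (degenerate variance)")
  (x - mean(obs)) / stats::sd(obs)
}

#' Fill interior gaps in a driver series by linear interpolation
#'
#' Interior runs of missing values are replaced by the straight line
#' between the flanking observations (via [zoo::na.approx()]).  Leading or
#' trailing gaps cannot be interpolated; they are left missing with a
#' warning.
#'
#' @param x numeric vector.
#' @return numeric vector with attribute `n_interpolated`, the count of
#'   filled values.
#' @export
interpolate_drivers <- function(x) {
  if (all(!is.finite(x))) stop("interpolate_drivers: all values missing")
  xx <- x
  xx[!is.finite(xx)] <- NA_real_
  filled <- as.numeric(zoo::na.approx(xx, na.rm = FALSE))
  n_new <- sum(is.na(xx) & !is.na(filled))
  if (anyNA(filled)) {
    warning("interpolate_drivers: leading/trailing gaps left missing (",
            sum(is.na(filled)), " values)")
  }
  attr(filled, "n_interpolated") <- n_new
  filled
}

#' Centred moving-average smoother
#'
#' Averages each point over a centred window of `window` months, matching
#' the temporal scale of moving-window network properties.  Edge points use
#' the truncated window (all available observations) rather than being
#' dropped, so early and late years are retained.  For even windows the
#' window extends `floor((window-1)/2)` months back and
#' `ceiling((window-1)/2)` forward.
#'
#' @param x numeric vector.
#' @param window window length in months (>= 1).
#' @return numeric vector of the same length.
#' @export
smooth_window <- function(x, window) {
  n <- length(x)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  if (window == 1) return(x)
  left <- floor((window - 1) / 2)
  right <- ceiling((window - 1) / 2)
  vapply(seq_len(n), function(t) {
    w <- x[max(1, t - left):min(n, t + right)]
    if (all(!is.finite(w))) NA_real_ else mean(w[is.finite(w)])
  }, numeric(1))
}

#' Aggregate taxa time series into guilds
#'
#' Sums member-taxon abundances per month for each guild.  A guild-month is
#' missing only when every member is missing; otherwise the sum of the
#' observed members is used (partial sums bias low but preserve dynamics).
#'
#' @param taxa data frame with a `month` column plus one numeric column per
#'   taxon.
#' @param guild_map named character vector: `names()` are taxon columns,
#'   values are guild ids.  Taxa absent from the map are dropped with a
#'   warning.
#' @return data frame with `month` plus one column per guild, with
#'   attribute `partial_months`: a named list of months where some (not
#'   all) members of a guild were missing.
#' @export
aggregate_guilds <- function(taxa, guild_map) {
  stopifnot(is.data.frame(taxa), "month" %in% names(taxa))
  taxon_cols <- setdiff(names(taxa), "month")
  unmapped <- setdiff(taxon_cols, names(guild_map))
  if (length(unmapped)) {
    warning("dropping unmapped taxa: ", paste(unmapped, collapse = ", "))
    taxon_cols <- setdiff(taxon_cols, unmapped)
  }
  if (!length(taxon_cols)) stop("no mapped taxa to aggregate")
  guilds <- unique(unname(guild_map[taxon_cols]))
  if (length(guilds) > 15) stop("guild count (", length(guilds), ") exceeds 15")
  out <- data.frame(month = taxa$month)
  partial <- list()
  for (g in guilds) {
    members <- taxon_cols[guild_map[taxon_cols] == g]
    block <- as.matrix(taxa[, members, drop = FALSE])
    n_obs <- rowSums(is.finite(block))
    s <- rowSums(block, na.rm = TRUE)
    s[n_obs == 0] <- NA_real_
    out[[g]] <- s
    part <- which(n_obs > 0 & n_obs < length(members))
    if (length(part)) partial[[g]] <- taxa$month[part]
  }
  attr(out, "partial_months") <- partial
  out
}
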