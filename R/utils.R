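#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Deterministic seed for an ordered variable pair
#'
#' Derives a per-pair seed from a master seed and a stable polynomial hash
#' of the "driver->driven" label, so results for one pair never change when
#' other pairs are added to or removed from an analysis.
#'
#' @param master integer master seed.
#' @param driver,driven character variable names.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
pair_seed <- function(master, driver, driven) {
  key <- paste0(driver, "\x01", driven)
  h <- 0
  mod <- 2147483647  # 2^31 - 1, keeps everything in integer range
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% mod
  as.integer((h + as.numeric(master)) %% mod)
}

#' Rolling-window Pearson correlation
#'
#' Correlation of two aligned series within every contiguous window of
#' `width` time steps, computed from cumulative sums so the cost is linear
#' in series length.  Pairs with a missing value in either series are
#' dropped within each window; windows with fewer than `min_pairs`
#' complete pairs, or zero variance, yield `NA`.
#'
#' @param x,y numeric vectors of equal length (may contain `NA`).
#' @param width window width in time steps.
#' @param min_pairs minimum number of complete pairs per window.
#' @return numeric vector of length `length(x) - width + 1`; element `i`
#'   is the correlation over positions `i:(i + width - 1)`.
#' @export
rolling_cor <- function(x, y, width, min_pairs = 3L) {
  n <- length(x)
  stopifnot(length(y) == n, width >= 1)
  if (width > n) stop("window width exceeds series length")
  okpair <- is.finite(x) & is.finite(y)
  xs <- ifelse(okpair, x, 0)
  ys <- ifelse(okpair, y, 0)
  cs <- function(v) cumsum(c(0, v))
  Sx <- cs(xs); Sy <- cs(ys); Sxx <- cs(xs^2); Syy <- cs(ys^2)
  Sxy <- cs(xs * ys); Sn <- cs(as.numeric(okpair))
  i <- seq_len(n - width + 1L)
  j <- i + width
  nn <- Sn[j] - Sn[i]
  sx <- Sx[j] - Sx[i]; sy <- Sy[j] - Sy[i]
  sxx <- Sxx[j] - Sxx[i]; syy <- Syy[j] - Syy[i]; sxy <- Sxy[j] - Sxy[i]
  num <- nn * sxy - sx * sy
  den2 <- (nn * sxx - sx^2) * (nn * syy - sy^2)
  out <- ifelse(nn >= min_pairs & den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  # numerical guard: clamp into [-1, 1]
  pmin(1, pmax(-1, out))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# seq() that is empty when to < from (safe integer ranges).
seq2 <- function(from, to) if (to < from) integer(0) else seq(from, to)

# Shared stamp arithmetic: centre of a window starting at `start` with the
# given width, integer floor of the midpoint (width 60 from start 1 -> 30).
window_centre <- function(start, width) {
  as.integer(floor((2 * start + width - 1) / 2))
}
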