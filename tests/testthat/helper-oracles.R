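# Independent reference implementations and shared fixtures.  The oracles
# are deliberately naive (double loops, stats::lm) so they share no code
# with the package kernels they check.

logistic_map <- function(n, r = 3.8, x0 = 0.23) {
  x <- numeric(n)
  x[1] <- x0
  for (t in seq_len(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  x
}

# Brute-force simplex projection with leave-one-out: all-pairs distances,
# full sort, exponential weights, weight floor as documented.
oracle_simplex <- function(x, E, tau = 1, tp = 1, k = E + 1,
                           exclusion_radius = 0) {
  n <- length(x)
  block <- sapply(seq_len(E), function(j) {
    lag <- (j - 1) * tau
    c(rep(NA_real_, lag), x[seq_len(n - lag)])
  })
  valid <- which(rowSums(is.finite(block)) == E)
  y <- rep(NA_real_, n)
  src <- seq_len(n) + tp
  ok <- src >= 1 & src <= n
  y[ok] <- x[src[ok]]
  lib <- valid[is.finite(y[valid])]
  pred_rows <- valid[is.finite(y[valid])]
  predictions <- observed <- rep(NA_real_, n)
  for (p in pred_rows) {
    d <- numeric(0); idx <- integer(0)
    for (l in lib) {
      if (l == p || abs(l - p) <= exclusion_radius) next
      d <- c(d, sqrt(sum((block[p, ] - block[l, ])^2)))
      idx <- c(idx, l)
    }
    if (length(idx) < k) next
    o <- order(d)[seq_len(k)]
    dd <- d[o]
    if (dd[1] > 0) {
      w <- exp(-dd / dd[1])
    } else {
      w <- ifelse(dd == 0, 1, 0)
    }
    w <- pmax(w, 1e-6 * max(w))
    predictions[p + tp] <- sum(w * y[idx[o]]) / sum(w)
    observed[p + tp] <- y[p]
  }
  okp <- is.finite(predictions) & is.finite(observed)
  list(predictions = predictions, observed = observed,
       rho = if (sum(okp) >= 3) cor(predictions[okp], observed[okp]) else NA)
}

# Two-species Ricker pair where the coupling of A onto B can be switched
# off at a change point (used for moving-window power checks).
ricker_pair <- function(n, c_ba = -0.35, switch_off_at = NULL, seed = 1,
                        noise = 0.02) {
  set.seed(seed)
  a <- b <- numeric(n)
  a[1] <- 0.7; b[1] <- 1.2
  for (t in seq_len(n - 1)) {
    cc <- if (!is.null(switch_off_at) && t >= switch_off_at) 0 else c_ba
    sa <- 1 + 0.25 * sin(2 * pi * (t - 4) / 12)
    sb <- 1 + 0.2 * sin(2 * pi * (t - 5) / 12)
    a[t + 1] <- a[t] * exp(2.9 * sa - 2.9 * a[t] + rnorm(1, 0, noise))
    b[t + 1] <- b[t] * exp(2.6 * sb - 2.6 * b[t] + cc * a[t] + rnorm(1, 0, noise))
  }
  list(a = a, b = b)
}

# Minimal hand-built ccm_network object for metric tests: `sig` is a
# named list driver->driven -> logical vector over windows, `strength`
# likewise (optional).
fake_net <- function(graph, centres, sig, strength = NULL) {
  rows <- lapply(names(sig), function(key) {
    pr <- strsplit(key, "->", fixed = TRUE)[[1]]
    s <- sig[[key]]
    st <- if (!is.null(strength)) strength[[key]] else ifelse(s, 0.5, 0)
    data.frame(driver = pr[1], driven = pr[2], window_centre = centres,
               local_rho = st, strength = st, significant = s,
               skipped = FALSE)
  })
  links <- do.call(rbind, rows)
  meta <- unique(links[, c("driver", "driven")])
  meta$E <- 3L; meta$convergent <- TRUE; meta$conv_p <- 0.01
  meta$whole_rho <- 0.5
  structure(list(links = links, meta = meta, graph = graph,
                 config = run_config()), class = "ccm_network")
}

# Small fully typed three-level graph used across metric tests.
toy_graph <- function() {
  nodes <- data.frame(guild = c("P", "G", "Z"),
                      trophic_level = c("producer", "grazer", "predator"),
                      class = c("producer", "grazer", "predator"))
  links <- data.frame(
    driver = c("P", "G", "G", "Z", "P", "Z"),
    driven = c("G", "P", "Z", "G", "Z", "P"),
    interaction_type = c("trophic", "trophic", "trophic", "trophic",
                         "hybrid", "hybrid"),
    trophic_direction = c("bottom_up", "top_down", "bottom_up", "top_down",
                          "bottom_up", "top_down"))
  guild_graph(nodes, links)
}
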