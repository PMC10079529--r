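# Collapse per-link moving-window results into network-property time
# series: connectance, mean interaction strength, trophic control,
# interaction-type structure, plus trend and group-comparison tests.

link_table <- function(net) {
  stopifnot(inherits(net, "ccm_network"))
  merge(net$links, net$graph$links, by = c("driver", "driven"),
        all.x = TRUE, sort = FALSE)
}

#' Network connectance time series
#'
#' Per window, the percentage of significant causal links among possible
#' links: `C = 100 * L / possible`.  The default denominator follows the
#' network-construction convention (candidate links of the template that
#' passed the convergence test); `all_ordered_pairs` uses `N (N - 1)`,
#' and `template_all` uses every candidate link regardless of
#' convergence.
#'
#' @param net a [build_network()] result.
#' @param mode one of `"template_links"` (default), `"template_all"`,
#'   `"all_ordered_pairs"`.
#' @return data frame `window_centre`, `connectance` (percent), with the
#'   denominator recorded in attribute `possible_links`.
#' @export
connectance <- function(net, mode = c("template_links", "template_all",
                                      "all_ordered_pairs")) {
  mode <- match.arg(mode)
  N <- nrow(net$graph$nodes)
  possible <- switch(mode,
    template_links = sum(net$meta$convergent),
    template_all = nrow(net$graph$links),
    all_ordered_pairs = N * (N - 1))
  if (possible == 0) stop("undefined connectance: zero possible links")
  L <- tapply(net$links$significant, net$links$window_centre, sum)
  out <- data.frame(window_centre = as.integer(names(L)),
                    connectance = 100 * as.numeric(L) / possible)
  out <- out[order(out$window_centre), ]
  rownames(out) <- NULL
  attr(out, "possible_links") <- possible
  attr(out, "mode") <- mode
  out
}

#' Mean interaction strength time series
#'
#' Per window, the mean surrogate-corrected strength over significant
#' links; `NA` where no link is significant.
#'
#' @param net a [build_network()] result.
#' @return data frame `window_centre`, `mean_strength`.
#' @export
mean_strength <- function(net) {
  l <- net$links
  agg <- tapply(seq_len(nrow(l)), l$window_centre, function(idx) {
    s <- l$strength[idx][l$significant[idx]]
    if (!length(s)) NA_real_ else mean(s)
  })
  out <- data.frame(window_centre = as.integer(names(agg)),
                    mean_strength = as.numeric(agg))
  out[order(out$window_centre), , drop = FALSE]
}

#' Trophic-control time series (top-down minus bottom-up)
#'
#' Restricted to trophic and hybrid links (the directed ones), computes
#' per window the top-down and bottom-up connectance (each normalized by
#' its own possible-link count) and mean strengths, and their
#' differences: values above zero indicate top-down control, below zero
#' bottom-up.  A class with no significant links in a window contributes
#' connectance 0 and strength `NA` (so the strength difference is `NA`).
#'
#' @param net a [build_network()] result.
#' @return data frame `window_centre`, `td_connectance`,
#'   `bu_connectance`, `td_minus_bu_connectance`, `td_strength`,
#'   `bu_strength`, `td_minus_bu_strength`.
#' @export
trophic_control <- function(net) {
  lt <- link_table(net)
  lt <- lt[lt$interaction_type %in% c("trophic", "hybrid"), ]
  poss_td <- n_candidate_links(net$graph, c("trophic", "hybrid"), "top_down")
  poss_bu <- n_candidate_links(net$graph, c("trophic", "hybrid"), "bottom_up")
  if (poss_td == 0 || poss_bu == 0)
    stop("graph lacks top-down or bottom-up candidate links")
  one <- function(dirn, poss) {
    d <- lt[lt$trophic_direction == dirn, ]
    conn <- tapply(d$significant, d$window_centre, sum) * 100 / poss
    stren <- tapply(seq_len(nrow(d)), d$window_centre, function(idx) {
      s <- d$strength[idx][d$significant[idx]]
      if (!length(s)) NA_real_ else mean(s)
    })
    data.frame(window_centre = as.integer(names(conn)),
               conn = as.numeric(conn), strength = as.numeric(stren))
  }
  td <- one("top_down", poss_td)
  bu <- one("bottom_up", poss_bu)
  m <- merge(td, bu, by = "window_centre", suffixes = c("_td", "_bu"))
  out <- data.frame(window_centre = m$window_centre,
                    td_connectance = m$conn_td,
                    bu_connectance = m$conn_bu,
                    td_minus_bu_connectance = m$conn_td - m$conn_bu,
                    td_strength = m$strength_td,
                    bu_strength = m$strength_bu,
                    td_minus_bu_strength = m$strength_td - m$strength_bu)
  out[order(out$window_centre), , drop = FALSE]
}

#' Per-interaction-type connectance and strength
#'
#' Per window and interaction type (trophic, non-trophic, hybrid):
#' connectance as percent of that type's candidate links, and mean
#' strength over the type's significant links (`NA` when none).
#'
#' @param net a [build_network()] result.
#' @return data frame `window_centre`, `interaction_type`,
#'   `n_significant`, `possible`, `connectance`, `mean_strength`.
#' @export
type_decomposition <- function(net) {
  lt <- link_table(net)
  types <- c("trophic", "non_trophic", "hybrid")
  out <- do.call(rbind, lapply(types, function(ty) {
    poss <- n_candidate_links(net$graph, ty)
    d <- lt[lt$interaction_type == ty, ]
    if (!nrow(d)) return(NULL)
    L <- tapply(d$significant, d$window_centre, sum)
    stren <- tapply(seq_len(nrow(d)), d$window_centre, function(idx) {
      s <- d$strength[idx][d$significant[idx]]
      if (!length(s)) NA_real_ else mean(s)
    })
    data.frame(window_centre = as.integer(names(L)),
               interaction_type = ty,
               n_significant = as.integer(L), possible = poss,
               connectance = 100 * as.numeric(L) / poss,
               mean_strength = as.numeric(stren))
  }))
  out[order(out$interaction_type, out$window_centre), , drop = FALSE]
}

#' Prevalence-weighted link strength
#'
#' Collapses one link's moving-window series to a scalar: the mean
#' strength over its significant windows multiplied by the fraction of
#' (non-skipped) windows in which it was significant.  Zero when never
#' significant.  This discounts strong but episodic effects.
#'
#' @param link data frame with columns `strength`, `significant` and
#'   optionally `skipped`.
#' @return scalar.
#' @export
prevalence_weighted_strength <- function(link) {
  stopifnot(all(c("strength", "significant") %in% names(link)))
  keep <- if ("skipped" %in% names(link)) !link$skipped else
    is.finite(link$strength)
  n <- sum(keep)
  if (n == 0) return(0)
  sig <- link$significant & keep
  if (!any(sig)) return(0)
  mean(link$strength[sig]) * (sum(sig) / n)
}

#' Monotonic trend test for a network property
#'
#' Spearman's rank correlation of a property series against time,
#' optionally restricted to a focal period (e.g. the re-oligotrophication
#' era before 2000 or the warming era after).
#'
#' @param values numeric property series.
#' @param time numeric time stamps (same length).
#' @param period optional `c(start, end)` limits on `time` (inclusive).
#' @return list with `estimate` (Spearman R), `p_value`, `n`.
#' @export
trend_test <- function(values, time, period = NULL) {
  stopifnot(length(values) == length(time))
  keep <- is.finite(values) & is.finite(time)
  if (!is.null(period)) keep <- keep & time >= period[1] & time <= period[2]
  v <- values[keep]; t <- time[keep]
  if (length(v) < 5) stop("fewer than 5 non-missing points in period")
  if (length(unique(v)) < 2) stop("undefined correlation: constant series")
  ct <- suppressWarnings(stats::cor.test(v, t, method = "spearman"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(v))
}

#' Pairwise Wilcoxon comparison of interaction types
#'
#' Rank-sum tests between interaction-type groups of per-lake mean
#' values (one unit per lake), for connectance or strength.  The exact
#' null distribution is used for group sizes up to 10 (no ties), the
#' normal approximation above.
#'
#' @param values numeric vector of per-lake means.
#' @param type factor/character of the same length giving the
#'   interaction type of each value.
#' @return data frame `type1`, `type2`, `statistic`, `p_value`, `n1`,
#'   `n2`.
#' @export
compare_types <- function(values, type) {
  stopifnot(length(values) == length(type))
  groups <- split(values[is.finite(values)], type[is.finite(values)])
  if (any(vapply(groups, length, 1L) < 3))
    stop("each interaction-type group needs >= 3 units")
  nm <- names(groups)
  combos <- utils::combn(nm, 2)
  out <- apply(combos, 2, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    exact <- length(a) <= 10 && length(b) <= 10 &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
    data.frame(type1 = pr[1], type2 = pr[2],
               statistic = unname(wt$statistic), p_value = wt$p.value,
               n1 = length(a), n2 = length(b))
  })
  do.call(rbind, out)
}

#' Collect the standard network-property series
#'
#' Convenience wrapper assembling connectance, mean strength and
#' trophic-control differences into one aligned data frame.
#'
#' @param net a [build_network()] result.
#' @param mode connectance denominator mode (see [connectance()]).
#' @return data frame keyed by `window_centre`.
#' @export
network_properties <- function(net, mode = "template_links") {
  cn <- connectance(net, mode)
  ms <- mean_strength(net)
  tc <- tryCatch(trophic_control(net), error = function(e) NULL)
  out <- merge(cn, ms, by = "window_centre")
  if (!is.null(tc)) {
    out <- merge(out,
                 tc[, c("window_centre", "td_minus_bu_connectance",
                        "td_minus_bu_strength")],
                 by = "window_centre", all.x = TRUE)
  }
  out[order(out$window_centre), , drop = FALSE]
}
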