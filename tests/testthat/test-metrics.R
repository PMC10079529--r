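test_that("connectance follows the percentage formula and its bounds", {
  g <- toy_graph()
  centres <- 1:3
  # no significant links -> 0%
  net0 <- fake_net(g, centres, list("P->G" = rep(FALSE, 3),
                                    "G->P" = rep(FALSE, 3)))
  expect_equal(connectance(net0, "template_all")$connectance, rep(0, 3))

  # all candidate links significant, all-ordered-pairs mode
  sig_all <- setNames(rep(list(rep(TRUE, 3))), NULL)
  sig <- lapply(seq_len(nrow(g$links)), function(i) rep(TRUE, 3))
  names(sig) <- paste0(g$links$driver, "->", g$links$driven)
  net1 <- fake_net(g, centres, sig)
  expect_equal(connectance(net1, "all_ordered_pairs")$connectance,
               rep(100, 3))
  expect_equal(connectance(net1, "template_all")$connectance, rep(100, 3))

  # L / (N (N-1)) arithmetic: 21 of 210 ordered pairs is 10%
  expect_equal(100 * 21 / (15 * 14), 10)

  # bounded and monotone: adding one significant link never lowers it
  sig2 <- sig
  sig2[["P->G"]] <- c(TRUE, TRUE, FALSE)
  net2 <- fake_net(g, centres, sig2)
  c2 <- connectance(net2, "template_all")$connectance
  c1 <- connectance(net1, "template_all")$connectance
  expect_true(all(c1 >= c2))
  expect_true(all(c2 >= 0 & c2 <= 100))

  # node relabeling leaves connectance unchanged
  g_re <- guild_graph(
    transform(g$nodes, guild = paste0(guild, "x")),
    transform(g$links, driver = paste0(driver, "x"),
              driven = paste0(driven, "x")))
  sig_re <- sig2
  names(sig_re) <- sub("->", "x->", names(sig_re), fixed = TRUE)
  names(sig_re) <- paste0(names(sig_re), "x")
  net_re <- fake_net(g_re, centres, sig_re)
  expect_equal(connectance(net_re, "template_all")$connectance, c2)
})

test_that("mean strength averages significant links, else missing", {
  g <- toy_graph()
  net <- fake_net(g, 1:2,
                  list("P->G" = c(TRUE, FALSE), "G->P" = c(TRUE, FALSE)),
                  list("P->G" = c(0.2, 0), "G->P" = c(0.6, 0)))
  ms <- mean_strength(net)
  expect_equal(ms$mean_strength[1], 0.4)
  expect_true(is.na(ms$mean_strength[2]))

  one <- fake_net(g, 1, list("P->G" = TRUE), list("P->G" = 0.4))
  expect_equal(mean_strength(one)$mean_strength, 0.4)
})

test_that("trophic control difference respects the sign convention", {
  g <- toy_graph()  # 3 bottom_up and 3 top_down candidates
  # only top-down links significant -> positive connectance difference
  td_only <- fake_net(g, 1:2, list(
    "G->P" = c(TRUE, TRUE), "Z->G" = c(TRUE, TRUE), "Z->P" = c(TRUE, TRUE),
    "P->G" = c(FALSE, FALSE), "G->Z" = c(FALSE, FALSE),
    "P->Z" = c(FALSE, FALSE)))
  tc <- trophic_control(td_only)
  expect_true(all(tc$td_minus_bu_connectance > 0))
  expect_equal(tc$td_connectance, rep(100, 2))
  expect_equal(tc$bu_connectance, rep(0, 2))
  # no significant bottom-up links: connectance 0, strength NA
  expect_true(all(is.na(tc$bu_strength)))
  expect_true(all(is.na(tc$td_minus_bu_strength)))

  # symmetric significance and equal strengths -> both differences zero
  symm <- fake_net(g, 1:2, setNames(rep(list(c(TRUE, TRUE)), 6),
                                    c("G->P", "Z->G", "Z->P",
                                      "P->G", "G->Z", "P->Z")))
  tcs <- trophic_control(symm)
  expect_equal(tcs$td_minus_bu_connectance, rep(0, 2))
  expect_equal(tcs$td_minus_bu_strength, rep(0, 2))
})

test_that("interaction-type decomposition recomposes total link counts", {
  g <- toy_graph()
  set.seed(30)
  sig <- lapply(seq_len(nrow(g$links)), function(i) runif(5) < 0.5)
  names(sig) <- paste0(g$links$driver, "->", g$links$driven)
  net <- fake_net(g, 1:5, sig)
  td <- type_decomposition(net)
  total_by_window <- tapply(td$n_significant, td$window_centre, sum)
  L <- tapply(net$links$significant, net$links$window_centre, sum)
  expect_equal(as.numeric(total_by_window), as.numeric(L))
  # weighted recomposition of overall connectance
  overall <- connectance(net, "template_all")$connectance
  recomposed <- tapply(td$connectance * td$possible, td$window_centre, sum) /
    nrow(g$links)
  expect_equal(as.numeric(recomposed), overall)

  # all-hybrid significance leaves other types at zero
  sig_h <- lapply(seq_len(nrow(g$links)), function(i)
    rep(g$links$interaction_type[i] == "hybrid", 2))
  names(sig_h) <- paste0(g$links$driver, "->", g$links$driven)
  net_h <- fake_net(g, 1:2, sig_h)
  td_h <- type_decomposition(net_h)
  expect_true(all(td_h$connectance[td_h$interaction_type == "trophic"] == 0))
  expect_true(all(td_h$connectance[td_h$interaction_type == "hybrid"] == 100))
})

test_that("prevalence weighting scales strength by occurrence", {
  allsig <- data.frame(strength = rep(0.5, 10), significant = TRUE,
                       skipped = FALSE)
  expect_equal(prevalence_weighted_strength(allsig), 0.5)
  half <- data.frame(strength = c(rep(0.6, 5), rep(0, 5)),
                     significant = c(rep(TRUE, 5), rep(FALSE, 5)),
                     skipped = FALSE)
  expect_equal(prevalence_weighted_strength(half), 0.3)
  never <- data.frame(strength = rep(0, 8), significant = FALSE,
                      skipped = FALSE)
  expect_equal(prevalence_weighted_strength(never), 0)
})

test_that("trend test matches a rank-based oracle and handles periods", {
  up <- c(1, 3, 4, 8, 9, 12)
  expect_equal(trend_test(up, seq_along(up))$estimate, 1)
  expect_equal(trend_test(rev(up), seq_along(up))$estimate, -1)

  # oracle: Spearman R via hand-computed ranks on a small fixture
  v <- c(3, 1, 4, 1.5, 5, 9, 2.6, 5.3)
  t <- 1:8
  oracle <- cor(rank(v), rank(t))
  expect_equal(trend_test(v, t)$estimate, oracle, tolerance = 1e-12)

  # period subsetting
  tt <- trend_test(c(v, 100, 101), c(t, 9, 10), period = c(1, 8))
  expect_equal(tt$n, 8)
  expect_equal(tt$estimate, oracle, tolerance = 1e-12)

  expect_error(trend_test(c(1, 2, 3), 1:3), "fewer than 5")
  expect_error(trend_test(rep(1, 6), 1:6), "constant")
})

test_that("pairwise type comparisons use the rank-sum distribution", {
  # disjoint-support groups of size 5: minimal attainable two-sided p
  vals <- c(1:5, 101:105, 6:10 + 0.5)
  type <- rep(c("trophic", "non_trophic", "hybrid"), each = 5)
  out <- compare_types(vals, type)
  row <- out[out$type1 == "non_trophic" & out$type2 == "trophic", ]
  expect_equal(row$p_value, 2 / choose(10, 5), tolerance = 1e-12)

  # near-identical groups do not reject
  set.seed(31)
  v2 <- rep(c(1, 2, 3, 4, 5), 3) + rnorm(15, 0, 1e-6)
  out2 <- compare_types(v2, type)
  expect_true(all(out2$p_value > 0.5))

  expect_error(compare_types(c(1, 2), c("a", "b")), ">= 3")
})
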