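# independent exact Mann-Whitney oracle: enumerate all assignments of the
# pooled midranks to the first group via combn
exact_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  sets <- utils::combn(length(pooled), na)
  mean(apply(sets, 2, function(ix) sum(r[ix])) >= w_obs - 1e-9)
}

test_that("ordering vectors follow day, estimate and expression order", {
  # all samples on one day: v_P equals v_G by the tie rule
  expr <- c(0.4, 0.1, 0.3, 0.2)
  v <- order_vectors(expr, rep(8L, 4), c(9, 6, 8, 7), "increasing")
  expect_equal(v$v_P, sort(expr))
  expect_equal(v$v_G, sort(expr))
  expect_equal(v$v_E, expr[order(c(9, 6, 8, 7))])

  # perfectly monotone expression over distinct days: all three agree
  days <- 4:9
  expr2 <- c(.1, .2, .35, .5, .7, .9)
  v2 <- order_vectors(expr2, days, as.numeric(days), "increasing")
  expect_equal(v2$v_P, expr2); expect_equal(v2$v_E, expr2)
  expect_equal(v2$v_G, expr2)
  # decreasing gene: v_G descends
  v3 <- order_vectors(expr2, days, as.numeric(days), "decreasing")
  expect_equal(v3$v_G, rev(expr2))

  # one tied day pair: the resolution concordant with v_G is chosen
  expr4 <- c(0.5, 0.2, 0.8, 0.35)
  days4 <- c(8L, 8L, 9L, 7L)
  v4 <- order_vectors(expr4, days4, c(8.1, 7.9, 9, 7), "increasing")
  # enumeration oracle over both resolutions of the day-8 tie
  res_a <- expr4[c(4, 1, 2, 3)]; res_b <- expr4[c(4, 2, 1, 3)]
  concordant <- if (sum(abs(sort(expr4) - res_a)) <= sum(abs(sort(expr4) - res_b)))
    res_a else res_b
  expect_equal(v4$v_P, concordant)
})

test_that("one-sided rank-sum p behaves at the extremes and matches enumeration", {
  # estimates recover the perfect order, reported times do not: small p
  v_G <- 1:10 / 10
  p <- wilcoxon_order_test(v_P = v_G[c(3, 1, 5, 2, 8, 4, 10, 6, 9, 7)],
                           v_E = v_G, v_G = v_G)
  expect_lt(p, 0.05)
  # identical orderings: p near one half
  p2 <- wilcoxon_order_test(v_G[c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)],
                            v_G[c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)], v_G)
  expect_gt(p2, 0.4); expect_lte(p2, 0.8)
  # both exactly perfect: no evidence, p = 1
  expect_equal(wilcoxon_order_test(v_G, v_G, v_G), 1)

  # frozen exact case: a = {5,6,7}, b = {1,2,3} -> 1/choose(6,3)
  p3 <- endotime:::exact_ranksum_p(c(5, 6, 7), c(1, 2, 3))
  expect_equal(p3, 0.05, tolerance = 1e-12)

  # exact DP equals full combn enumeration on random tied instances
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    a <- sample(0:5, n, replace = TRUE) / 4   # ties within and across groups
    b <- sample(0:5, n, replace = TRUE) / 4
    expect_equal(endotime:::exact_ranksum_p(a, b), exact_p_oracle(a, b),
                 tolerance = 1e-9)
  }

  # large-n path agrees with the tie-corrected normal approximation
  set.seed(62)
  va <- abs(runif(25)); vb <- abs(runif(25)) * 0.3
  p_pkg <- wilcoxon_order_test(v_P = va, v_E = vb, v_G = rep(0, 25))
  p_ref <- stats::wilcox.test(va, vb, alternative = "greater",
                              exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("the day-tie resolution minimizes deviation from the perfect order", {
  # Within-day ties are resolved in the gene's direction; by the
  # rearrangement inequality this makes sum|v_G - v_P| minimal over every
  # possible resolution of the ties (the most favourable reading of the
  # reported times). Verified here by exhaustive enumeration.
  set.seed(63)
  for (rep in 1:20) {
    n <- 8
    days <- sort(c(sample(4:9, 5), sample(4:9, 3)))   # forces a few ties
    expr <- runif(n)
    eLH <- days + runif(n, -0.4, 0.4)
    v <- order_vectors(expr, days, eLH, "increasing")
    dev_chosen <- sum(abs(v$v_G - v$v_P))
    groups <- split(seq_len(n), days)
    perms_of <- function(ix) {
      if (length(ix) == 1) return(list(ix))
      do.call(c, lapply(seq_along(ix), function(i)
        lapply(perms_of(ix[-i]), function(rest) c(ix[i], rest))))
    }
    group_perms <- lapply(groups, perms_of)
    combos <- expand.grid(lapply(group_perms, seq_along))
    for (ci in seq_len(nrow(combos))) {
      ordering <- unlist(lapply(seq_along(groups), function(gi)
        group_perms[[gi]][[combos[ci, gi]]]))
      expect_gte(sum(abs(v$v_G - expr[ordering])), dev_chosen - 1e-9)
    }
  }
})

test_that("Bonferroni correction is exact, capped and monotone", {
  expect_equal(bonferroni_adjust(0.01, m = 6), 0.06)
  expect_equal(bonferroni_adjust(0.5, m = 6), 1)
  expect_equal(bonferroni_adjust(c(1e-4, 0.02, 0.2)), c(3e-4, 0.06, 0.6))
  # agrees with p.adjust and is monotone (order-preserving up to the cap)
  set.seed(64)
  p <- runif(6)
  expect_equal(bonferroni_adjust(p), stats::p.adjust(p, "bonferroni"))
  expect_true(all(diff(bonferroni_adjust(p)[order(p)]) >= 0))
})

test_that("leave-one-out runs are isolated from the held-out gene", {
  sim <- small_sim(n = 80, seed = 41)
  cfg <- small_config(seed = 41)
  panel <- preprocess_cohort(sim$cohort, cfg)
  fit5 <- loo_estimate(panel, sim$cohort$reported_day, "GPX3", cfg)
  expect_false("GPX3" %in% names(fit5$profiles))
  # perturbing the held-out column changes nothing
  panel2 <- panel
  panel2$expr[, "GPX3"] <- rev(panel2$expr[, "GPX3"])
  fit5b <- loo_estimate(panel2, sim$cohort$reported_day, "GPX3", cfg)
  expect_identical(fit5b$records$eLH, fit5$records$eLH)
  # 5-gene ordering tracks the 6-gene ordering
  fit6 <- run_endotime(panel, sim$cohort$reported_day, cfg)
  expect_gt(stats::cor(fit5$records$eLH, fit6$records$eLH,
                       method = "spearman"), 0.9)
  # holding out each gene yields one timing vector per gene
  lv <- loo_validate(panel, sim$cohort$reported_day, cfg)
  expect_identical(lv$gene, names(cfg$panel_genes))
  expect_true(all(lv$p_raw > 0 & lv$p_raw <= 1))
  expect_true(all(lv$p_adj >= lv$p_raw))
  expect_error(loo_estimate(panel, sim$cohort$reported_day, "NOPE", cfg),
               "NOPE")
})

test_that("panel reduction tolerates redundancy and sheds uninformative genes", {
  sim <- small_sim(n = 80, seed = 42)
  cfg <- small_config(seed = 42)
  panel <- preprocess_cohort(sim$cohort, cfg)

  # dropping an exact duplicate barely moves the inferred ordering
  dup <- panel
  dup$expr <- cbind(dup$expr, DUP = dup$expr[, "CXCL14"])
  dup$directions <- c(dup$directions, DUP = "increasing")
  cfg_dup <- cfg
  cfg_dup$panel_genes <- dup$directions
  fit7 <- run_endotime(dup, sim$cohort$reported_day, cfg_dup)
  fit6 <- run_endotime(panel, sim$cohort$reported_day, cfg)
  expect_gt(stats::cor(rank(fit7$records$eLH), rank(fit6$records$eLH),
                       method = "spearman"), 0.99)
  red <- reduce_panel(dup, sim$cohort$reported_day, target_size = 6L, cfg_dup)
  expect_identical(nrow(red$removed), 1L)
  expect_gt(red$removed$correlation, 0.95)     # whatever leaves is near-redundant

  # target equal to current size: nothing to do
  red0 <- reduce_panel(panel, sim$cohort$reported_day, target_size = 6L, cfg)
  expect_identical(nrow(red0$removed), 0L)
  expect_identical(red0$final_genes, colnames(panel$expr))

  # an unreachable correlation floor stops the reduction with a warning
  expect_warning(
    red_stop <- reduce_panel(panel, sim$cohort$reported_day,
                             target_size = 2L, cfg, corr_floor = 0.99999),
    "stopping")
  expect_gt(length(red_stop$final_genes), 2L)

  # pure-noise genes dominate the early removals
  removed_genes <- character()
  for (seed in 43:44) {
    simn <- simulate_cohort(default_sim_spec(n_samples = 150, rng_seed = seed))
    cfgn <- endotime_config(window_start = 24L, window_step = 4L,
                            window_min = 8L, converge = 1, rng_seed = seed)
    pn <- preprocess_cohort(simn$cohort, cfgn)
    set.seed(seed * 10)
    for (nm in paste0("NZ", 1:4)) {
      pn$expr <- cbind(pn$expr, runif(150))
      colnames(pn$expr)[ncol(pn$expr)] <- nm
      pn$directions <- c(pn$directions, stats::setNames("increasing", nm))
    }
    cfgn$panel_genes <- pn$directions
    redn <- reduce_panel(pn, simn$cohort$reported_day, target_size = 6L, cfgn)
    removed_genes <- c(removed_genes, redn$removed$gene)
  }
  expect_gte(sum(grepl("^NZ", removed_genes)), length(removed_genes) / 2)
})

test_that("PCA variance check recovers planted structure", {
  set.seed(51)
  t <- runif(30, 4, 12)
  # rank-1 data varying only along time
  loadings <- rnorm(40)
  m1 <- outer(loadings, t)
  pv <- suppressWarnings(pca_time_variance(m1, t))
  expect_gt(pv$var_explained[1], 0.999)
  expect_gt(pv$time_correlation, 0.999)

  # isotropic noise with random timings: no dominant axis (the top-two
  # fraction stays near the random-matrix level, far below planted
  # structure), and no alignment with the timings
  m2 <- matrix(rnorm(200 * 30), 200, 30)
  pv2 <- pca_time_variance(m2, runif(30, 4, 12))
  expect_lt(pv2$pc12_fraction, 0.2)
  expect_lt(pv2$time_correlation, 0.6)

  # duplicating every gene leaves the variance fractions unchanged,
  # matching a direct eigendecomposition oracle
  m3 <- rbind(m1 + rnorm(1200, 0, 0.5), m1 + rnorm(1200, 0, 0.5))
  pv3 <- pca_time_variance(m3, t)
  cen <- scale(t(m3), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(cen), symmetric = TRUE)$values
  expect_equal(pv3$var_explained, (ev / sum(ev))[1:2], tolerance = 1e-9)
  expect_error(pca_time_variance(m1[, 1:2], t[1:2]), "at least 3")
})
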