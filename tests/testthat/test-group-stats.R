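test_that("IQR fences reproduce hand-computed quartile fences", {
  r <- iqr_filter(c(1, 2, 3, 4, 100), k = 3)
  # Q1 = 2, Q3 = 4 by linear interpolation; fences [-4, 10]
  expect_equal(r$kept, c(1, 2, 3, 4))
  expect_equal(r$removed, 100)
  q <- quantile(c(1, 2, 3, 4, 100), c(0.25, 0.75), names = FALSE)
  expect_equal(q, c(2, 4))

  same <- iqr_filter(rep(7, 10), k = 3)
  expect_equal(same$kept, rep(7, 10))
  expect_length(same$removed, 0)

  wide <- iqr_filter(c(-50, 1, 2, 3, 4, 900), k = 1e9)
  expect_equal(wide$kept, c(-50, 1, 2, 3, 4, 900))

  expect_warning(few <- iqr_filter(c(1, 1000), k = 3), "fewer than 4")
  expect_equal(few$kept, c(1, 1000))

  # order preserved
  set.seed(2)
  v <- c(rnorm(20), 50, rnorm(5))
  kept <- iqr_filter(v, 3)$kept
  expect_identical(kept, v[v != 50])
})

test_that("one-way ANOVA matches brute-force sums of squares to 1e-10", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:9, 1), mean = i / 2))
    got <- one_way_anova(groups)
    want <- oracle_anova(groups)
    expect_lt(abs(got$statistic - want$f), 1e-10 * max(1, want$f))
    expect_lt(abs(got$p_value - want$p), 1e-10)
  }
})

test_that("ANOVA symmetry and degenerate conventions hold", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(one_way_anova(g)$statistic, 0)
  expect_equal(one_way_anova(g[c(3, 1, 2)])$statistic, 0)
  perm <- one_way_anova(list(c(5, 6), c(7, 8), c(9, 10)))
  expect_equal(perm$statistic,
               one_way_anova(list(c(9, 10), c(5, 6), c(7, 8)))$statistic)
  expect_equal(one_way_anova(list(c(2, 2), c(2, 2)))$p_value, 1)
  expect_equal(one_way_anova(list(c(2, 2), c(3, 3)))$p_value, 0)
})

test_that("exact Mann-Whitney matches full enumeration for all n <= 5", {
  set.seed(23)
  for (na in 1:5) for (nb in 1:5) for (rep in 1:3) {
    pool <- sample(seq(1, 500), na + nb)   # tie-free
    a <- pool[1:na]; b <- pool[(na + 1):(na + nb)]
    got <- mann_whitney_u(a, b)
    want <- oracle_mw_exact(a, b)
    expect_true(got$exact)
    expect_equal(unname(got$statistic), want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d rep=%d", na, nb, rep))
  }
})

test_that("Mann-Whitney handles canonical cases and the approximate path", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(sep$statistic), 0)
  expect_equal(sep$p_value, 0.1)

  id <- mann_whitney_u(c(4, 5, 6, 7), c(4, 5, 6, 7))
  expect_equal(unname(id$statistic), 8)   # n_a * n_b / 2
  expect_equal(id$p_value, 1)
  expect_false(id$exact)                  # ties force the approximation

  devs <- vapply(1:50, function(s) {
    set.seed(s)
    a <- rnorm(7); b <- rnorm(7, 1)
    exact <- mann_whitney_u(a, b, exact = TRUE)
    approx <- mann_whitney_u(a, b, exact = FALSE)
    abs(exact$p_value - approx$p_value)
  }, numeric(1))
  expect_lt(max(devs), 0.015)
  expect_lt(median(devs), 0.01)
  set.seed(31)
  a <- rnorm(7); b <- rnorm(7, 1)
  expect_equal(mann_whitney_u(a, b, exact = TRUE)$p_value,
               oracle_mw_exact(a, b)$p)
})

test_that("the comparison plan gates follow-ups on the month-7 ANOVA per site", {
  set.seed(41)
  # strong attenuation effect at the back only
  eff <- study_effect_profile("mu_mm_inv",
                              month7_targets = c(control = 41.5,
                                                 uvr_control = 21.5,
                                                 uvr_nmn = 21.5, uvr_pl = 21.5),
                              site_weight = c(back = 1, side = 0, stomach = 0),
                              months = c(0, 7))
  ser <- simulate_metric_series("mu_mm_inv", eff, n_mice = 6)
  res <- run_comparison_plan(ser, alpha = 0.05)
  anova7 <- res[res$test == "anova" & res$month_a == 7, ]
  mw_sites <- unique(res$site[res$test == "mann_whitney"])
  expect_setequal(mw_sites, anova7$site[anova7$p_value < 0.05])
  expect_true("back" %in% mw_sites)
  expect_lt(anova7$p_value[anova7$site == "back"], 0.001)
  # follow-up set at a gated site: 4 within-group + 3 control-vs + 2 uvr-vs
  expect_equal(sum(res$test == "mann_whitney" & res$site == "back"), 9)

  # alpha = 1 opens the gate everywhere
  all_sites <- run_comparison_plan(ser, alpha = 1)
  expect_setequal(unique(all_sites$site[all_sites$test == "mann_whitney"]),
                  c("back", "side", "stomach"))

  # missing cells are named
  expect_error(run_comparison_plan(ser[ser$group != "uvr_pl", ], alpha = 1),
               "uvr_pl")
  gap <- ser[!(ser$month == 7 & ser$site == "side"), ]
  expect_error(run_comparison_plan(gap, alpha = 1), "side, month 7")
})

test_that("IQR outliers are removed per cell before Mann-Whitney tests", {
  set.seed(43)
  eff <- study_effect_profile("mu_mm_inv", months = c(0, 7))
  ser <- simulate_metric_series("mu_mm_inv", eff, n_mice = 6, noise_sd = 0.2)
  ser$value[ser$group == "control" & ser$site == "back" & ser$month == 7][1] <- 500
  res <- run_comparison_plan(ser, alpha = 1)
  row <- res[res$site == "back" & res$comparison == "control_vs_uvr_control", ]
  expect_equal(row$n_outliers_removed, 1)
  expect_equal(row$n_a, 5)
})

test_that("longitudinal summaries report monthly means and linear trends", {
  months <- 0:7
  recs <- expand.grid(mouse = 1:3, group = "control", site = "back",
                      month = months, stringsAsFactors = FALSE)
  recs$mouse_id <- sprintf("m%d", recs$mouse)
  recs$value <- 5
  flat <- metric_series("mu_mm_inv",
                        recs[c("mouse_id", "group", "site", "month", "value")])
  s <- longitudinal_summary(flat)
  expect_true(all(s$means$mean_value == 5))
  expect_equal(s$trends$slope, 0)

  recs$value <- 10 + 2.5 * recs$month
  ramp <- metric_series("mu_mm_inv",
                        recs[c("mouse_id", "group", "site", "month", "value")])
  expect_equal(longitudinal_summary(ramp)$trends$slope, 2.5)

  # UV-like decline is steeper (more negative) than a flat control
  set.seed(47)
  worse <- 0
  for (r in 1:100) {
    eff <- study_effect_profile("mu_mm_inv")
    ser <- simulate_metric_series("mu_mm_inv", eff, n_mice = 6)
    tr <- longitudinal_summary(ser)$trends
    s_ctrl <- tr$slope[tr$group == "control" & tr$site == "back"]
    s_uvr <- tr$slope[tr$group == "uvr_control" & tr$site == "back"]
    worse <- worse + (s_uvr < s_ctrl)
  }
  expect_gte(worse, 95)
})
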