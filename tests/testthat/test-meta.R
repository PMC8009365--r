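test_that("shift rates and specialist percentages reproduce the published rows", {
  # the published 2-dp value for 23 shifts / 22 taxa is 1.04; the exact
  # quotient is 1.0455, so agreement is asserted at the percent level
  expect_equal(shift_rate(23, 22), 1.04, tolerance = 0.01)
  expect_equal(round(shift_rate(9, 7), 2), 1.29)
  expect_equal(shift_rate(0, 50), 0)
  expect_equal(shift_rate(15.9, 10), 1.5)  # censored counts floored first
  expect_error(shift_rate(-1, 10), "negative")
  expect_equal(round(specialists_pct(23, 51)), 45)
  expect_equal(round(specialists_pct(12, 22)), 55)
  expect_equal(specialists_pct(0, 7), 0)
  expect_error(specialists_pct(8, 7), "between")
})

test_that("group summaries reproduce the published medians and quartiles", {
  st <- biome_shift_studies()
  single <- st[!st$multiple_biomes, ]
  multi <- st[st$multiple_biomes, ]
  gs <- group_summary(single$shift_rate)
  expect_equal(gs$median, 0.04)
  expect_equal(gs$n, 9L)
  rates_multi <- shift_rate(multi$shift_count, multi$clade_size)
  gm <- group_summary(rates_multi)
  expect_equal(round(gm$median, 2), 0.55)
  expect_equal(round(gm$q3, 2), 0.75)
  expect_equal(gm$n, 16L)
  # single element and permutation invariance
  expect_equal(group_summary(0.3), list(median = 0.3, q1 = 0.3, q3 = 0.3, n = 1L))
  set.seed(5)
  x <- runif(11)
  expect_equal(group_summary(x), group_summary(sample(x)))
})

test_that("the one-tailed Welch test reproduces the published comparison", {
  st <- biome_shift_studies()
  a <- st$shift_rate[!st$multiple_biomes]
  b <- st$shift_rate[st$multiple_biomes & !st$nz]
  w <- welch_one_tailed(a, b)
  expect_equal(round(w$statistic, 2), 3.20)
  expect_equal(w$df_display, 7)
  expect_lt(w$p, 0.01)
  # identical groups: t = 0, p = 0.5
  w0 <- welch_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 0.5)
})

test_that("welch and paired statistics equal brute-force formula evaluation", {
  set.seed(19)
  for (rep in 1:10) {
    a <- rnorm(7); b <- rnorm(9, 0.5)
    w <- welch_one_tailed(a, b)
    o <- oracle_welch(a, b)
    expect_equal(w$statistic, o$t, tolerance = 1e-12)
    expect_equal(w$df, o$df, tolerance = 1e-12)
    expect_equal(w$p, o$p, tolerance = 1e-12)
    # the two directional p-values are complementary for continuous data
    expect_equal(welch_one_tailed(a, b)$p + welch_one_tailed(b, a)$p, 1,
                 tolerance = 1e-12)
    s <- rnorm(8); m <- s + rnorm(8, 0.3)
    p <- paired_one_tailed(s, m)
    po <- oracle_paired(s, m)
    expect_equal(p$statistic, po$t, tolerance = 1e-12)
    expect_equal(p$p, po$p, tolerance = 1e-12)
    expect_equal(p$df, 7L)
  }
})

test_that("degenerate paired differences are guarded, not fatal", {
  expect_equal(paired_one_tailed(c(1, 2, 3), c(1, 2, 3)),
               list(statistic = 0, df = 2L, p = 0.5, tails = "one",
                    paired = TRUE))
  up <- paired_one_tailed(c(1, 2, 3), c(2, 3, 4))  # constant +1
  expect_true(is.infinite(up$statistic) && up$statistic > 0)
  expect_equal(up$p, 0)
  dn <- paired_one_tailed(c(2, 3, 4), c(1, 2, 3))
  expect_equal(dn$p, 1)
})

test_that("the regression helper matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5)
  # a perfectly collinear fixture triggers lm's perfect-fit warning
  expect_equal(suppressWarnings(ols_fit(x, 2 * x + 1)$r_squared), 1)
  expect_equal(ols_fit(c(-1, 0, 1), c(1, -2, 1))$slope, 0, tolerance = 1e-12)
  expect_equal(ols_fit(c(-1, 0, 1), c(1, -2, 1))$r_squared, 0, tolerance = 1e-12)
  set.seed(23)
  for (rep in 1:5) {
    xx <- rnorm(12); yy <- 0.4 * xx + rnorm(12)
    f <- ols_fit(xx, yy)
    o <- oracle_ols(xx, yy)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r2, tolerance = 1e-10)
    expect_equal(f$F, (o$r2 / (1 - o$r2)) * 10, tolerance = 1e-10)
    expect_equal(sort(f$qq$sample), sort(f$residuals))
  }
})

test_that("the proportional decline reproduces the published extremes", {
  expect_equal(b_decline(0.72, 0.62)$B_decline, 0.1389, tolerance = 1e-4)
  expect_equal(b_decline(0.72, 0.62)$percent, 14)
  expect_equal(b_decline(0.55, 0.18)$percent, 67)
  expect_equal(b_decline(0.5, 0.5)$B_decline, 0)
  for (r in c(0.1, 0.7, 1.3)) {
    expect_equal(b_decline(r, r)$B_decline, 0)
    expect_equal(b_decline(r, 0)$B_decline, 1)
  }
  expect_error(b_decline(0, 0.1), "> 0")
})

test_that("diversification rates reproduce the published table values", {
  expect_equal(round(diversification_rate(124, 10.21, "stem"), 2), 0.47)
  expect_equal(round(diversification_rate(7, 2.00, "crown"), 2), 0.63)
  expect_equal(diversification_rate(2, 5, "crown"), 0)
  # epsilon correction reduces to the simple forms at 0 and lowers the rate
  expect_lt(diversification_rate(50, 10, "stem", epsilon = 0.5),
            diversification_rate(50, 10, "stem"))
  expect_lt(diversification_rate(50, 10, "crown", epsilon = 0.5),
            diversification_rate(50, 10, "crown"))
})

test_that("the packaged tables pass their schema checks and drive the full report", {
  st <- biome_shift_studies()
  expect_equal(nrow(st), 25L)
  expect_equal(sum(st$nz), 9L)
  expect_equal(sum(st$censored), 2L)
  ages <- nz_clade_ages()
  expect_equal(nrow(ages), 9L)
  rep <- meta_report()
  expect_equal(rep$decline_range, c(14, 67))
  expect_equal(round(rep$welch_non_nz$statistic, 2), 3.20)
  expect_equal(rep$welch_non_nz$df_display, 7)
  expect_equal(rep$paired$df, 8L)
  expect_gt(rep$paired$statistic, 0)
  tend <- rep$tendency
  expect_equal(tend$absolute_change[tend$clade == "Coprosma"], 0.27)
  expect_equal(round(tend$percent_change[tend$clade == "Coprosma"]), 47)
  expect_true(is.na(tend$percent_change[tend$clade == "Myrsine"]))
  div <- rep$diversification
  expect_equal(round(div$rate[div$clade == "Veronica"], 2), 0.47)
  expect_equal(round(div$rate[div$clade == "Rytidosperma B"], 2), 0.63)
})
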