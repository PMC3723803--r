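test_that("noiseless single-slope data give equal segment slopes and deviance 0", {
  aoa <- 5:30
  d <- aoa_data(aoa, 200 - 1.5 * aoa)
  fit <- fit_breakpoint(d, breakpoint = 15)
  ct <- suppressWarnings(coef_table(fit))  # vcov warns on a perfect fit
  expect_equal(ct$estimate[2], -1.5, tolerance = 1e-9)
  expect_equal(ct$estimate[3], -1.5, tolerance = 1e-9)
  expect_equal(deviance(fit), 0, tolerance = 1e-16)
})

test_that("breakpoint fits match the 3-column normal-equation oracle and join", {
  for (seed in 1:20) {
    d <- random_dataset(withr::with_seed(seed, sample(10:50, 1)),
                        seed = seed + 300)
    bp <- withr::with_seed(seed + 600, {
      sample(seq(quantile(d$aoa, 0.25), quantile(d$aoa, 0.75)), 1)
    })
    ok <- length(unique(d$aoa[d$aoa <= bp])) >= 2 &&
      length(unique(d$aoa[d$aoa > bp])) >= 2
    if (!ok) next
    fit <- fit_breakpoint(d, bp)
    orc <- oracle_ols(design_breakpoint(d$aoa, bp), d$gjt)
    expect_rel_equal(coef(fit$model), orc$beta, 1e-10)
    expect_rel_equal(deviance(fit), orc$rss, 1e-10)
    # joined at the breakpoint: both segment lines meet there
    ct <- coef_table(fit)
    before_at_bp <- ct$estimate[1] + ct$estimate[2] * 0
    after_at_bp <- ct$estimate[1] + ct$estimate[3] * 0
    expect_lt(abs(before_at_bp - after_at_bp), 1e-9)
    # and the fitted mean is continuous across the breakpoint
    eps <- 1e-9
    pred <- aoabreak:::predict_mean(fit, c(bp - eps, bp + eps))
    expect_lt(abs(pred[1] - pred[2]), 1e-6)
    # adding the breakpoint regressor can never increase the deviance
    expect_lte(deviance(fit), deviance(fit_ols(d)) + 1e-9)
  }
})

test_that("segment underflow raises an error", {
  d <- aoa_data(c(5, 20, 25, 30, 35), c(190, 170, 165, 160, 150))
  expect_error(fit_breakpoint(d, 10), "segment underflow")
})

test_that("the scan finds an exact kink and reports per-candidate oracle deviances", {
  d <- kinked_dataset(bp = 10, s1 = 0, s2 = -1.5, aoa = 4:40)
  prof <- scan_breakpoints(d, 5, 19)
  expect_equal(optimal_breakpoint(prof), 10)
  expect_equal(prof$deviance[prof$breakpoint == 10], 0, tolerance = 1e-16)
  expect_equal(prof$breakpoint, 5:19)
  for (i in seq_len(nrow(prof))) {
    orc <- oracle_ols(design_breakpoint(d$aoa, prof$breakpoint[i]), d$gjt)
    expect_equal(prof$deviance[i], orc$rss, tolerance = 1e-9)
  }
})

test_that("exact deviance ties are broken towards the smallest breakpoint", {
  # noiseless linear data: every candidate reaches deviance 0, a full tie
  aoa <- 3:40
  d <- aoa_data(aoa, 200 - aoa)
  prof <- scan_breakpoints(d, 5, 19)
  expect_equal(max(prof$deviance), 0, tolerance = 1e-16)
  expect_equal(optimal_breakpoint(prof), 5)
})

test_that("unfittable candidates are dropped with a warning, empty grids error", {
  d <- aoa_data(c(10, 11, 12, 20, 30, 40), c(180, 178, 176, 160, 140, 120))
  expect_warning(prof <- scan_breakpoints(d, 5, 19), "dropping")
  expect_false(any(prof$breakpoint < 11))
  expect_error(suppressWarnings(scan_breakpoints(d, 41, 50)), "no candidate")
})

test_that("the nested comparison matches anova() and the direct F formula", {
  d <- random_dataset(40, seed = 11)
  simple <- fit_ols(d)
  bp <- fit_breakpoint(d, 18)
  cmp <- compare_nested(simple, bp)
  # independent route: R's anova on the two underlying linear models
  a <- anova(simple$model, bp$model)
  expect_equal(cmp$f_stat, a$F[2], tolerance = 1e-10)
  expect_equal(cmp$p_one_tailed, a$`Pr(>F)`[2], tolerance = 1e-10)
  # direct formula from the two deviances
  f_direct <- ((deviance(simple) - deviance(bp)) / 1) /
    (deviance(bp) / (nrow(d) - 3))
  expect_equal(cmp$f_stat, f_direct, tolerance = 1e-12)
  expect_equal(cmp$df1, 1)
  expect_equal(cmp$df2, nrow(d) - 3)
  expect_true(cmp$preferred %in% c("simple", "breakpoint"))
  expect_identical(cmp$preferred,
                   if (cmp$p_one_tailed < 0.05) "breakpoint" else "simple")
})

test_that("the nested comparison rejects fits on different datasets", {
  d1 <- random_dataset(30, seed = 1)
  d2 <- random_dataset(32, seed = 2)
  expect_error(compare_nested(fit_ols(d1), fit_breakpoint(d2, 18)),
               "mismatch")
  expect_error(compare_nested(fit_breakpoint(d1, 18), fit_breakpoint(d1, 18)))
})

test_that("confidence bands shrink with noise, are narrowest at the mean age, and match the oracle", {
  # near-noiseless data: band width collapses towards 0
  aoa <- 5:30
  d_tiny <- aoa_data(aoa, 200 - aoa + withr::with_seed(4, rnorm(26, 0, 1e-6)))
  band <- confidence_band(fit_ols(d_tiny))
  expect_lt(max(band$upper - band$lower), 1e-5)

  d <- random_dataset(30, seed = 21)
  fit <- fit_ols(d)
  grid <- seq(min(d$aoa), max(d$aoa), by = 0.5)
  band <- confidence_band(fit, grid = grid)
  widths <- band$upper - band$lower
  expect_equal(grid[which.min(widths)], grid[which.min(abs(grid - mean(d$aoa)))],
               tolerance = 0.51)

  # oracle: t quantile * sqrt(x0' (X'X)^-1 x0 * sigma2)
  d10 <- random_dataset(10, seed = 33)
  fit10 <- fit_ols(d10)
  orc <- oracle_ols(design_simple(d10$aoa, 18), d10$gjt)
  g <- sort(unique(d10$aoa))
  se_orc <- sqrt(orc$sigma2 *
                   rowSums((design_simple(g, 18) %*% orc$XtX_inv) *
                             design_simple(g, 18)))
  b10 <- confidence_band(fit10, grid = g, level = 0.95)
  tq <- qt(0.975, nrow(d10) - 2)
  expect_equal(b10$upper - b10$fit, tq * se_orc, tolerance = 1e-9)

  expect_warning(confidence_band(fit10, grid = c(1, 80)), "outside")
})
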