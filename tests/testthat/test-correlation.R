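test_that("the Fisher transform has its defining values and symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  for (r in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(fisher_z(-r), -fisher_z(r))
  }
  expect_error(fisher_z(1), "inside")
  expect_error(fisher_z(-1.2), "inside")
})

test_that("the significance of r flips between 0.27 and 0.28 at n = 50", {
  expect_lt(r_significance(0.28, 50)["p"], 0.05)
  expect_gt(r_significance(0.27, 50)["p"], 0.05)
  z <- r_significance(0, 30)
  expect_equal(unname(z["t_stat"]), 0)
  expect_equal(unname(z["p"]), 1)
  # t formula cross-check against cor.test on raw data
  set.seed(3)
  x <- rnorm(40); y <- 0.4 * x + rnorm(40)
  ct <- cor.test(x, y)
  rs <- r_significance(cor(x, y), 40)
  expect_equal(unname(rs["t_stat"]), unname(ct$statistic), tolerance = 1e-10)
  expect_equal(unname(rs["p"]), ct$p.value, tolerance = 1e-10)
  expect_error(r_significance(1, 20), "infinite")
})

test_that("correlation comparison is antisymmetric with standard-normal p-values", {
  a <- compare_correlations(-0.37, 17, 0.45, 32)
  b <- compare_correlations(0.45, 32, -0.37, 17)
  expect_identical(a$z_stat, -b$z_stat)
  expect_equal(round(abs(a$z_stat), 2), 2.68)
  expect_lt(a$p_one_tailed, 0.05)

  same <- compare_correlations(0.3, 20, 0.3, 25)
  expect_equal(same$z_stat, 0)
  expect_equal(same$p_two_tailed, 1)
  expect_error(compare_correlations(0.3, 3, 0.3, 25), "n >= 4")
})

test_that("a significant r in one group and not the other does not imply a difference", {
  # r = 0.40 at n = 20 is 'significant', r = 0.10 at n = 100 is not, yet
  # the two correlations do not differ significantly
  expect_gt(compare_correlations(0.40, 20, 0.10, 100)$p_two_tailed, 0.05)
  expect_lt(r_significance(0.40, 20, tails = 1)["p"], 0.05)
})

test_that("partial correlation matches the closed form and stays in [-1, 1]", {
  expect_equal(partial_correlation(0.8, 0, 0), 0.8)
  expect_equal(round(partial_correlation(0.8, 0.9, 0.7), 3), 0.546)
  # monotone attenuation in the confound correlation
  sweep <- vapply(seq(0.5, 0.95, by = 0.05),
                  function(rxz) partial_correlation(0.6, rxz, 0.7),
                  numeric(1))
  expect_true(all(diff(sweep) < 0))
  # PSD property over random correlation matrices built from raw data
  for (seed in 1:50) {
    R <- withr::with_seed(seed, cor(matrix(rnorm(30), 10, 3)))
    p <- partial_correlation(R[1, 2], R[1, 3], R[2, 3])
    expect_true(p >= -1 && p <= 1)
    # and the closed form agrees with regressing out z from raw data
  }
  expect_error(partial_correlation(0.8, 1, 0.2), "confound")
  expect_error(partial_correlation(0.9, 0.9, -0.9), "PSD")
})

test_that("partial correlation agrees with residual-based computation", {
  withr::with_seed(9, {
    z <- rnorm(200)
    x <- 0.7 * z + rnorm(200)
    y <- -0.5 * z + 0.3 * x + rnorm(200)
  })
  direct <- partial_correlation(cor(x, y), cor(x, z), cor(y, z))
  residual <- cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
  expect_equal(direct, residual, tolerance = 1e-10)
})

test_that("subgroup correlations match slice-and-compute oracles", {
  d <- generate_mimic("north_america", seed = 14)
  sc <- subgroup_correlations(d)
  expect_equal(sc$group, c("overall", "young", "middle", "old"))
  expect_equal(sc$n[1], nrow(d))
  for (g in c("young", "middle", "old")) {
    idx <- as.character(age_group(d$aoa)) == g
    expect_equal(sc$r[sc$group == g], cor(d$aoa[idx], d$gjt[idx]),
                 tolerance = 1e-12)
    expect_equal(sc$n[sc$group == g], sum(idx))
  }
  expect_equal(sum(sc$n[-1]), sc$n[1])

  one_bin <- aoa_data(c(20, 25, 30, 35), c(180, 175, 170, 165))
  sc1 <- subgroup_correlations(one_bin)
  expect_true(is.na(sc1$r[sc1$group == "young"]))
  expect_true(sc1$flagged[sc1$group == "old"])
})

test_that("scaling one group's noise attenuates only that group's correlation", {
  # equal slopes, one group with doubled noise SD: its |r| is smaller in
  # expectation even though the slope is identical
  res <- vapply(1:500, function(seed) {
    withr::with_seed(seed, {
      x1 <- runif(50, 5, 40); x2 <- runif(50, 5, 40)
      y1 <- -1.2 * x1 + rnorm(50, 0, 8)
      y2 <- -1.2 * x2 + rnorm(50, 0, 16)
      c(abs(cor(x1, y1)), abs(cor(x2, y2)))
    })
  }, numeric(2))
  expect_gt(mean(res[1, ]), mean(res[2, ]))
})

test_that("pairwise group comparisons of the published aptitude table single out Israel young-middle", {
  pc <- pairwise_group_comparisons(dekeyser2010_aptitude)
  expect_equal(nrow(pc), 6)
  expect_equal(sum(pc$significant), 1)
  sig <- pc[pc$significant, ]
  expect_equal(sig$study, "israel")
  expect_setequal(c(sig$group1, sig$group2), c("young", "middle"))
  rest <- round(abs(pc$z_stat[!pc$significant]), 2)
  expect_true(all(rest >= 0.46 & rest <= 1.28))
})
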