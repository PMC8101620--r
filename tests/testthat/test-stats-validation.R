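test_that("accuracy calibration matches the closed-form regression and
           the published worked example", {
  # perfectly linear pairs
  df <- tibble::tibble(ct = 1:10, ref = 3 + 2 * (1:10))
  ac <- accuracy_calibration(df, ct, ref)
  expect_equal(ac$r, 1)
  expect_equal(ac$slope, 2, tolerance = 1e-12)
  expect_equal(ac$intercept, 3, tolerance = 1e-12)

  # random pairs against the normal-equation oracle
  set.seed(9)
  x <- rnorm(40, 100, 15); y <- 5 + 0.6 * x + rnorm(40, 0, 4)
  ac2 <- accuracy_calibration(tibble::tibble(ct = x, ref = y), ct, ref)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(ac2$slope, b, tolerance = 1e-9)
  expect_equal(ac2$intercept, a, tolerance = 1e-9)
  # centroid identity: predicting at the CT mean returns the reference mean
  expect_equal(predict(ac2, mean(x)), mean(y), tolerance = 1e-9)

  # the published calibration lines reproduce the reference means from
  # the CT means (trabecular thickness and network area rows)
  tab <- study_table("accuracy")
  pred <- tab$calib_intercept + tab$calib_slope * tab$ct_mean
  th <- tab[tab$measure == "Tb.Th", ]
  expect_equal(round(th$calib_intercept + th$calib_slope * th$ct_mean, 1),
               th$reference_mean)
  na <- tab[tab$measure == "Tb.NA", ]
  expect_equal(round(na$calib_intercept + na$calib_slope * na$ct_mean, 2),
               na$reference_mean)
  # and every row lands within printed rounding of its reference mean
  expect_true(all(abs(pred - tab$reference_mean) <
                    pmax(0.005, 0.005 * abs(tab$reference_mean))))

  expect_error(accuracy_calibration(tibble::tibble(ct = c(1, 1, 1),
                                                   ref = 1:3), ct, ref),
               class = "bonemicro_degenerate")
})

test_that("one-way ICC recovers variance ratios and respects affine
           invariance", {
  # identical replicates with between-unit spread: ICC = 1
  m <- matrix(rep(rnorm(12, 10, 3), 3), ncol = 3)
  r1 <- icc_oneway(m)
  expect_equal(r1$icc, 1, tolerance = 1e-9)

  # simulated variance ratio 0.8 at n = 200, k = 3
  tab <- simulate_measure_table(n_per_group = 200, k_replicates = 3,
                                sigma_between = sqrt(0.8),
                                sigma_within = sqrt(0.2), seed = 7)
  r2 <- icc_oneway(tab, unit_id, value)
  expect_lt(abs(r2$icc - 0.8), 0.05)
  expect_lte(r2$ci_low, r2$icc)
  expect_gte(r2$ci_high, r2$icc)

  # pure noise: ICC near zero, CI covers 0
  tab0 <- simulate_measure_table(n_per_group = 200, k_replicates = 3,
                                 sigma_between = 0, sigma_within = 1,
                                 seed = 8)
  r3 <- icc_oneway(tab0, unit_id, value)
  expect_lt(r3$ci_low, 0.02)
  expect_lt(abs(r3$icc), 0.1)

  # invariance under y -> a + b y (b > 0)
  tab_t <- tab
  tab_t$value <- 5 + 3 * tab_t$value
  r4 <- icc_oneway(tab_t, unit_id, value)
  expect_equal(r4$icc, r2$icc, tolerance = 1e-9)

  cst <- matrix(1, 10, 3)
  expect_error(icc_oneway(cst), class = "bonemicro_degenerate")
})

test_that("unadjusted comparisons reproduce the published effect sizes
           and a hand-computed t-test", {
  # printed fracture-group summaries: d = mean difference / pooled SD
  tab <- study_table("fracture_groups")
  recomputed <- round(tab$mean_difference / tab$pooled_sd, 2)
  key <- tab$measure %in% c("Tb.vBMD", "Tb.tBMD", "Tb.PW", "Tb.Sp")
  expect_equal(recomputed[key], tab$effect_size[key])

  # identical groups: difference 0, effect size 0, p = 1
  df <- tibble::tibble(value = rep(c(1, 2, 3), 2),
                       group = rep(c(0, 1), each = 3))
  gc0 <- unadjusted_group_compare(df, value, group)
  expect_equal(gc0$mean_difference, 0)
  expect_equal(gc0$effect_size, 0)
  expect_equal(gc0$t_p_value, 1)

  # {1,2,3} vs {4,5,6}: t = -3.674, p = 0.02131 (pooled, df = 4)
  df2 <- tibble::tibble(value = c(1, 2, 3, 4, 5, 6),
                        group = rep(c("a", "b"), each = 3))
  gc <- unadjusted_group_compare(df2, value, group)
  expect_equal(gc$mean_difference, -3)
  expect_equal(gc$pooled_sd, 1)
  expect_equal(gc$effect_size, -3)
  expect_equal(gc$t_p_value, 2 * pt(-3 / (1 * sqrt(1 / 3 + 1 / 3)), 4),
               tolerance = 1e-12)
})

test_that("LS-means comparisons adjust for covariates and reduce to the
           unadjusted case when the covariate is balanced", {
  # balanced binary covariate: LS means equal raw means
  set.seed(3)
  n <- 40
  df <- tibble::tibble(
    group = rep(c(0, 1), each = n / 2),
    covariate = rep(c(0, 1), times = n / 2),
    value = 10 + 5 * group + 2 * covariate + rnorm(n, 0, 0.5))
  al <- adjusted_lsmeans(df, value, group, "covariate")
  raw <- tapply(df$value, df$group, mean)
  expect_equal(al$ls_mean_1, unname(raw[1]), tolerance = 1e-9)
  expect_equal(al$ls_mean_2, unname(raw[2]), tolerance = 1e-9)

  # parameter recovery: group effect 10, covariate effect 5
  tab <- simulate_measure_table(n_per_group = c(60, 60), group_effect = 10,
                                covariate_effect = 5, sigma_between = 0,
                                sigma_within = 2, seed = 12)
  al2 <- adjusted_lsmeans(tab, value, group, "covariate")
  ci_half <- 2.1 * al2$se
  expect_lt(abs(al2$ls_mean_difference - (-10)), ci_half)
  expect_equal(sign(al2$effect_size), sign(al2$ls_mean_difference))

  # constant covariate: rank-deficiency error
  tab_c <- tab
  tab_c$covariate <- 1
  expect_error(adjusted_lsmeans(tab_c, value, group, "covariate"),
               class = "bonemicro_rank_deficient")
})

test_that("noncentral-t power reproduces the published values and is
           monotone", {
  expect_equal(ttest_power(0, 9, 21), 0.05, tolerance = 1e-9)
  expect_equal(round(ttest_power(1.0, 9, 21), 2), 0.68)
  expect_equal(round(ttest_power(1.10, 9, 21), 2), 0.76)
  expect_gt(ttest_power(1.15, 9, 21), ttest_power(1.10, 9, 21))
  d <- seq(0.2, 2, by = 0.2)
  expect_true(all(diff(vapply(d, ttest_power, numeric(1),
                              n1 = 9, n2 = 21)) > 0))
  expect_gt(ttest_power(1, 18, 42), ttest_power(1, 9, 21))
})

test_that("Spearman association uses average ranks and matches a
           hand-ranked example", {
  expect_equal(spearman_assoc(tibble::tibble(a = 1:10, b = (1:10)^3),
                              a, b)$rho, 1)
  expect_equal(spearman_assoc(tibble::tibble(a = 1:10, b = -(1:10)),
                              a, b)$rho, -1)
  # tied example: x = (1,2,2,3), y = (10,20,20,40)
  # average ranks x: 1, 2.5, 2.5, 4; y: 1, 2.5, 2.5, 4 -> rho = 1
  expect_equal(spearman_assoc(tibble::tibble(a = c(1, 2, 2, 3),
                                             b = c(10, 20, 20, 40)),
                              a, b)$rho, 1)
  # mixed ties against a brute-force rank correlation
  x <- c(1, 2, 2, 3, 5); y <- c(2, 1, 4, 4, 5)
  rho_oracle <- cor(rank(x), rank(y))
  expect_equal(spearman_assoc(tibble::tibble(a = x, b = y), a, b)$rho,
               rho_oracle, tolerance = 1e-12)
  expect_error(spearman_assoc(tibble::tibble(a = rep(1, 5), b = 1:5),
                              a, b),
               class = "bonemicro_degenerate")
})
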