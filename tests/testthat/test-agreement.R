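test_that("limits of agreement follow mean +/- 1.96 SD", {
  expect_equal(round(loa_from_moments(0.76, 1.25), 2),
               c(lower = -1.69, upper = 3.21))
  expect_equal(round(loa_from_moments(-0.01, 2.58), 2),
               c(lower = -5.07, upper = 5.05))
  expect_equal(loa_from_moments(0, 0), c(lower = 0, upper = 0))
  expect_error(loa_from_moments(1, -0.1), ">= 0")
})

test_that("Bland-Altman matches a first-principles recomputation", {
  set.seed(81)
  m1 <- rnorm(20, 90, 15)
  m2 <- m1 - 1.5 + rnorm(20, 0, 2)
  ba <- bland_altman(m1, m2)
  or <- ba_sums_oracle(m1, m2)
  expect_equal(ba$bias, or$bias, tolerance = 1e-12)
  expect_equal(ba$sd_diff, or$sd_diff, tolerance = 1e-12)
  expect_equal(ba$prop_bias_slope, or$slope, tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  # t-based bias CI
  expect_equal(ba$bias_ci_high - ba$bias,
               qt(0.975, 19) * ba$sd_diff / sqrt(20))

  # degenerate: identical tools
  ba0 <- bland_altman(m1, m1)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_equal(ba0$prop_bias_slope, 0)
  expect_error(bland_altman(1:2, 1:2), "insufficient data")
})

test_that("Bland-Altman recovers simulated population bias and LoA", {
  p <- simulate_rater_pairs(1e4, truth_mean_deg = 90, truth_sd_deg = 20,
                            bias_deg = 2, diff_sd_deg = 3, seed = 82)
  ba <- bland_altman(p$tool1, p$tool2)
  expect_lt(abs(ba$bias - 2), 0.1)
  expect_lt(abs(ba$loa_low - (2 - 1.96 * 3)), 0.15)
  expect_lt(abs(ba$loa_high - (2 + 1.96 * 3)), 0.15)
})

test_that("ICC(2,1) equals the independent ANOVA oracle and honors df conventions", {
  # 5 x 2 hand-sized matrix against the aov decomposition
  m <- matrix(c(9, 10, 6, 8, 7, 7, 12, 11, 10, 12), 5, 2, byrow = TRUE)
  fit <- icc21(m)
  expect_equal(fit$icc, icc21_aov_oracle(m), tolerance = 1e-12)
  expect_equal(fit$df1, 4)
  expect_equal(fit$df2, 4)
  expect_equal(fit$f, fit$msr / fit$mse)

  # 100 random matrices within 1e-9
  set.seed(83)
  for (i in 1:100) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 50, 10), n, k)
    expect_equal(icc21(m)$icc, icc21_aov_oracle(m), tolerance = 1e-9)
  }

  # identical columns with row variance: perfect agreement
  v <- c(10, 20, 30, 40, 55)
  expect_equal(icc21(cbind(v, v))$icc, 1)

  # df = (n-1, n-1) for k = 2: the two-tool per-repetition convention
  m81 <- simulate_two_way(81, 2, 3, 0.5, 0.5, seed = 84)
  f81 <- icc21(m81)
  expect_equal(c(f81$df1, f81$df2), c(80, 80))
  m84 <- simulate_two_way(84, 2, 3, 0.5, 0.5, seed = 85)
  expect_equal(c(icc21(m84)$df1, icc21(m84)$df2), c(83, 83))

  expect_error(icc21(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc21(matrix(c(1, 2, NA, 4, 5, 6), 3, 2)), "incomplete")
})

test_that("ICC estimator recovers the population variance ratio", {
  set.seed(86)
  # high-reliability regime (the regime of interest): mean estimate over
  # replicate panels within 0.01 of the population ratio
  for (comp in list(c(9, 0.5, 0.5), c(4, 0.2, 0.8))) {
    pop <- comp[1] / sum(comp)
    est <- replicate(600, icc21(simulate_two_way(
      2000, 2, sqrt(comp[1]), sqrt(comp[2]), sqrt(comp[3])))$icc)
    expect_lt(abs(mean(est) - pop), 0.01)
  }
  # at low population ICC with only k = 2 raters the single rater-pair
  # draw enters as a skewed chi-square(1) term, leaving a small positive
  # finite-k bias that does not vanish with n; it stays below 0.05
  est <- replicate(200, icc21(simulate_two_way(
    2000, 2, 1, sqrt(0.5), sqrt(0.5)))$icc)
  bias <- mean(est) - 0.5
  expect_gt(bias, 0)
  expect_lt(bias, 0.05)
})

test_that("SEM, MDC and the interpretation bands follow the reliability equations", {
  expect_equal(sem_from(10, 0.75), 5)
  expect_equal(sem_from(7, 1), 0)
  expect_equal(sem_from(23.79, 0.95), 5.319, tolerance = 1e-3)
  expect_error(sem_from(10, 1.2), "<= 1")
  expect_error(sem_from(-1, 0.5), ">= 0")

  expect_equal(round(mdc_from(11.78), 2), 32.65)
  expect_equal(round(mdc_from(9.12), 2), 25.28)
  expect_equal(mdc_from(0), 0)

  # chained identity, exact
  sd <- 14.3; icc <- 0.87
  expect_identical(mdc_from(sem_from(sd, icc)),
                   (sd * sqrt(1 - icc)) * sqrt(2) * 1.96)

  expect_equal(interpret_icc(c(0.99, 0.81, 0.77, 0.61, 0.50, 0.30, 0.10)),
               c("excellent", "excellent", "good", "good", "moderate",
                 "fair", "poor"))
  # printed band edges leave gaps; gaps resolve to the lower band
  expect_equal(interpret_icc(0.805), "good")
  expect_equal(interpret_icc(0.205), "poor")
})

test_that("reliability() pools the SD by default and echoes it", {
  m <- simulate_two_way(27, 3, 8, 1, 2, grand_mean = 100, seed = 87)
  rel <- reliability(m)
  expect_equal(rel$sd_used, sd(as.numeric(m)))
  expect_equal(rel$sem, rel$sd_used * sqrt(1 - rel$icc$icc))
  expect_equal(rel$mdc, rel$sem * sqrt(2) * 1.96)
})

test_that("agreement report mirrors the task/joint row structure and composes with direct calls", {
  df <- simulate_agreement_dataset(n_participants = 9, n_reps = 3,
                                   sides = c("left", "right"),
                                   setting = "lab", seed = 88)
  rep_tab <- agreement_report(df)
  # 7 rows per side: task 1 shoulder-only, tasks 2-4 shoulder + elbow
  expect_equal(nrow(rep_tab), 14)
  for (side in c("left", "right")) {
    sub <- rep_tab[rep_tab$side == side, ]
    expect_equal(nrow(sub), 7)
    expect_equal(nrow(sub[sub$task == 1, ]), 1)
    expect_equal(sub$joint[sub$task == 1], "shoulder")
  }

  # single-group report agrees with direct estimator calls
  g <- df[df$side == "left" & df$task == 1 & df$joint == "shoulder", ]
  single <- agreement_report(g)
  v1 <- g$angle_deg[g$tool == "tool1"]
  v2 <- g$angle_deg[g$tool == "tool2"]
  ba <- bland_altman(v1, v2)
  ic <- icc21(cbind(v1, v2))
  expect_equal(single$bias, ba$bias)
  expect_equal(single$loa_low, ba$loa_low)
  expect_equal(single$icc, ic$icc)
  expect_equal(single$icc_ci_low, ic$ci_low)
  expect_equal(single$sem, sem_from(sd(c(v1, v2)), ic$icc))

  # insufficient group is skipped with a reason, not dropped
  g2 <- g[g$participant %in% 1 & g$rep %in% 1:2, ]
  skipped <- agreement_report(g2)
  expect_equal(nrow(skipped), 1)
  expect_match(skipped$note, "insufficient")
  expect_true(is.na(skipped$icc))
})

test_that("test-retest reliability report treats repetitions as raters", {
  df <- simulate_agreement_dataset(n_participants = 13, n_reps = 3,
                                   sides = "right", setting = "home",
                                   seed = 89)
  rel <- reliability_report(df, tool = "tool1")
  expect_equal(nrow(rel), 7)
  expect_true(all(rel$k == 3))
  expect_true(all(rel$n == 13))
  expect_equal(rel$mdc, rel$sem * sqrt(2) * 1.96)

  # one group checked against a direct matrix computation
  g <- df[df$tool == "tool1" & df$task == 3 & df$joint == "elbow", ]
  mat <- matrix(NA_real_, 13, 3)
  for (i in 1:13) for (r in 1:3) {
    mat[i, r] <- g$angle_deg[g$participant == i & g$rep == r]
  }
  direct <- reliability(mat)
  row <- rel[rel$task == 3 & rel$joint == "elbow", ]
  expect_equal(row$icc, direct$icc$icc)
  expect_equal(row$sem, direct$sem)
})

test_that("LoA coverage approaches the nominal 95 per cent", {
  p <- simulate_rater_pairs(2e4, bias_deg = 1, diff_sd_deg = 2, seed = 90)
  ba <- bland_altman(p$tool1, p$tool2)
  inside <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_lt(abs(inside - 0.95), 0.01)
})
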