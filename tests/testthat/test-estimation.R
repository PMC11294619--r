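test_that("pooled t-test matches the closed form and its edge cases", {
  # closed form: pooled variance 1, SE sqrt(2/3)
  tt <- unpaired_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(tt$df, 4)

  # agreement with the direct formula on random samples
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(4, 0.5)
    tt <- unpaired_t(a, b)
    sp2 <- ((5 * var(a) + 3 * var(b)) / 8)
    t_direct <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 4))
    expect_equal(tt$t, t_direct, tolerance = 1e-10)
    expect_equal(tt$p, 2 * pt(-abs(t_direct), 8), tolerance = 1e-10)
  }

  # identical samples: t = 0, p = 1 (zero pooled variance, equal means)
  expect_equal(unpaired_t(c(2, 2, 2), c(2, 2))[c("t", "p")],
               list(t = 0, p = 1))
  expect_error(unpaired_t(c(1, 1, 1), c(2, 2)), "infinite")

  # antisymmetry
  a <- rnorm(5); b <- rnorm(5, 1)
  expect_equal(unpaired_t(a, b)$t, -unpaired_t(b, a)$t)
  expect_equal(unpaired_t(a, b)$p, unpaired_t(b, a)$p)

  expect_error(unpaired_t(1, c(1, 2)), "n >= 2")
})

test_that("t-test holds its nominal type-I error rate under the null", {
  set.seed(20260924)
  rej <- mean(vapply(1:10000, function(i) {
    unpaired_t(rnorm(6), rnorm(4))$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("bootstrap mean difference: determinism, degenerate case, bundle", {
  g <- generate_group_table(6, 4, 100, -30, 8, seed = 2)
  ctrl <- g$table$value[g$table$group == "control"]
  tst <- g$table$value[g$table$group == "test"]

  b1 <- bootstrap_mean_diff(ctrl, tst, n_resamples = 2000, seed = 5)
  b2 <- bootstrap_mean_diff(ctrl, tst, n_resamples = 2000, seed = 5)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$resample_distribution, b2$resample_distribution)
  expect_equal(b1$mean_diff, mean(tst) - mean(ctrl))
  expect_true(b1$ci_low <= b1$mean_diff && b1$mean_diff <= b1$ci_high)
  expect_equal(length(b1$resample_distribution), 2000L)

  # degenerate: both groups a constant -> zero difference, [0, 0] CI
  for (m in c("percentile", "bca", "studentized")) {
    bd <- bootstrap_mean_diff(rep(3, 4), rep(3, 5), n_resamples = 1000,
                              method = m, seed = 1)
    expect_equal(bd$mean_diff, 0)
    expect_equal(c(bd$ci_low, bd$ci_high), c(0, 0))
  }

  expect_warning(bootstrap_mean_diff(ctrl, tst, n_resamples = 500, seed = 1),
                 "unstable")

  # Gardner-Altman bundle is a faithful pass-through
  ga <- export_gardner_altman(b1)
  expect_equal(c(ga$ci_low, ga$ci_high), c(b1$ci_low, b1$ci_high))
  expect_equal(length(ga$resample_distribution), b1$n_resamples)
  expect_equal(ga$diff_axis_origin, mean(ctrl))
  expect_equal(ga$group_stats$n, c(6L, 4L))
  # null comparison: effect marker at 0
  bn <- bootstrap_mean_diff(rep(c(1, 2), 3), rep(c(1, 2), 2),
                            n_resamples = 1000, seed = 9)
  expect_equal(export_gardner_altman(bn)$mean_diff, 0)
})

test_that("studentized bootstrap CI holds near-nominal coverage at small n", {
  # 400 simulated experiments at the study geometry (n = 6 vs 4, SD 8);
  # binomial SE at 0.95 over 400 sims is ~0.011
  cov <- mean(vapply(1:400, function(s) {
    g <- generate_group_table(6, 4, 100, -30, 8, seed = s)
    ctrl <- g$table$value[g$table$group == "control"]
    tst <- g$table$value[g$table$group == "test"]
    b <- bootstrap_mean_diff(ctrl, tst, n_resamples = 1000,
                             method = "studentized", seed = s + 40000L)
    b$ci_low <= -30 && -30 <= b$ci_high
  }, logical(1)))
  expect_gte(cov, 0.91)
  expect_lte(cov, 0.99)
})

test_that("z-score profile standardises against the control group", {
  # hand computation: controls {10,12,14} (sd 2), test value 16 -> z = 2
  tab <- data.frame(
    group = c("control", "control", "control", "test"),
    hemisphere = c("c1", "c2", "c3", "t1"),
    variable = "v",
    value = c(10, 12, 14, 16))
  pr <- zscore_profile(tab)
  expect_equal(unname(pr$z["control_mean", "v"]), 0)
  expect_equal(unname(pr$z["t1", "v"]), 2)

  # affine invariance: z unchanged under x -> a x + b, a > 0
  tab2 <- tab; tab2$value <- 3.5 * tab$value + 11
  expect_equal(zscore_profile(tab2)$z, pr$z)

  # control-only table: all-zero mean-control row
  tabc <- tab[1:3, ]
  prc <- zscore_profile(tabc)
  expect_true(all(prc$z["control_mean", ] == 0))

  # per-hemisphere control rows when not collapsed
  pr2 <- zscore_profile(tab, collapse_control = FALSE)
  expect_equal(unname(pr2$z["c2", "v"]), 0)  # c2 sits at the control mean
  expect_equal(mean(pr2$z[c("c1", "c2", "c3"), "v"]), 0)

  # zero-SD variable is dropped with a warning, others survive
  tab3 <- rbind(tab,
                data.frame(group = c("control", "control", "test"),
                           hemisphere = c("c1", "c2", "t1"),
                           variable = "flat", value = c(5, 5, 7)))
  expect_warning(pr3 <- zscore_profile(tab3), "zero control SD")
  expect_equal(pr3$dropped, "flat")
  expect_equal(pr3$variables, "v")

  expect_error(zscore_profile(tab, control_label = "nope"), "control label")
  expect_error(zscore_profile(tab[c(1, 4), ]), "< 2 control")
})
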