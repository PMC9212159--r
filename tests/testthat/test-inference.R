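test_that("plug-in t-test reproduces its defining p-values and edge cases", {
  # the three independently printed (value, p) anchors that pin the rule down
  expect_equal(round(plugin_cor_test(0.61, 18), 3), 0.004)
  expect_equal(round(plugin_cor_test(0.43, 18), 2), 0.04)
  expect_equal(round(plugin_cor_test(0.65, 18), 3), 0.002)
  expect_equal(plugin_cor_test(0, 18), 0.5)
  expect_equal(plugin_cor_test(1, 18), 0)
  expect_equal(plugin_cor_test(-1, 18, "two.sided"), 0)
  expect_error(plugin_cor_test(1.2, 18), "<= 1")
  expect_error(plugin_cor_test(0.5, 2), ">= 3")
})

test_that("plug-in p decreases in the measure and in the sample size", {
  ms <- seq(0.05, 0.95, by = 0.1)
  ps <- vapply(ms, plugin_cor_test, numeric(1), n = 18)
  expect_true(all(diff(ps) < 0))
  ns <- c(5, 10, 18, 40, 100)
  pn <- vapply(ns, function(n) plugin_cor_test(0.4, n), numeric(1))
  expect_true(all(diff(pn) < 0))
})

test_that("per-replicate significance applies the Bonferroni threshold", {
  expect_true(plugin_significant(0.78, 18))          # p ~ 1.4e-4 < 5e-4
  expect_false(plugin_significant(0.43, 18))         # p ~ 0.04
  expect_true(plugin_significant(1, 18, threshold = 1e-12))
  # threshold is the exceedance boundary
  expect_false(plugin_significant(0.43, 18, threshold = 0.03))
  expect_true(plugin_significant(0.43, 18, threshold = 0.05))
})

test_that("replicate t-test matches the closed-form Cauchy tail at R = 2", {
  s <- replicate_ttest(c(0.8, 0.9))
  expect_equal(s$mean, 0.85)
  expect_equal(s$se, 0.05)
  expect_equal(s$statistic, 17)
  # df = 1 Student t is Cauchy: two-sided p = 2*(0.5 - atan(t)/pi)
  expect_equal(s$p_value, 2 * (0.5 - atan(17) / pi))
  expect_equal(round(replicate_ttest(c(0.76, 0.88))$p_value, 3),
               round(2 * (0.5 - atan(0.82 / 0.06) / pi), 3))
})

test_that("replicate t-test is order-invariant and flags degeneracy", {
  v <- c(0.2, 0.5, 0.9, -0.1)
  expect_equal(replicate_ttest(v)$p_value,
               replicate_ttest(rev(v))$p_value)
  expect_warning(s0 <- replicate_ttest(c(0.9, 0.9)), "zero standard error")
  expect_equal(s0$p_value, 0)
  expect_equal(s0$se, 0)
})

test_that("replicate-averaged kernelized correlation recovers a noiseless value", {
  truth <- simulate_case(1, a = 1, noise = 0)
  spec <- kernel_spec("rbf", gamma = 0.5, standardize = FALSE)
  kc_true <- kernel_cor(truth$x, truth$y, spec)
  set.seed(31)
  reps <- lapply(1:4, function(i)
    list(x = truth$x + 0.05 * rnorm(18), y = truth$y + 0.05 * rnorm(18)))
  s <- kc_replicates(reps, spec)
  expect_lte(abs(s$mean - kc_true), 3 * s$se + 0.02)
  expect_equal(s$df, 3L)
  # identical replicates: mean 1 with the degenerate-se path
  same <- list(list(x = truth$x, y = truth$x),
               list(x = truth$x, y = truth$x))
  expect_warning(s1 <- kc_replicates(same, spec), "zero standard error")
  expect_equal(s1$mean, 1)
})

test_that("self-correlation screen flags identical profiles and rarely flags noise", {
  t5 <- c(0, 12, 24, 48, 72)
  prof <- 100 + 80 * sin(pi * t5 / 72)
  expect_warning(res <- self_cor_screen(list(prof, prof), list(prof, prof)),
                 "zero standard error")
  expect_true(res$flagged)
  expect_equal(res$self_correlation, 1)
  # independent noise in the two conditions: flag rate stays low
  set.seed(99)
  flags <- replicate(100, {
    ca <- lapply(1:2, function(i) rnorm(5))
    cb <- lapply(1:2, function(i) rnorm(5))
    self_cor_screen(ca, cb)$flagged
  })
  expect_lt(mean(flags), 0.10)
})
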