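test_that("generators satisfy their noiseless identities", {
  c1 <- simulate_case(1, a = 1, noise = 0)
  expect_equal(c1$x[1], -0.5)                 # 2*sin(0) - 0.5
  expect_equal(c1$times, seq(0, 119, by = 7))
  c3 <- simulate_case(3, a = 1, noise = 0)
  expect_equal(c3$y - c3$x, rep(3, 18))
  c2 <- simulate_case(2, a = 1, noise = 0)
  expect_equal(c2$x, 2 * c2$y)
})

test_that("null generator is centered: Case 2, a = 0, c = 1", {
  set.seed(123)
  draws <- replicate(10000, simulate_case(2, a = 0, noise = 1)$x[1])
  expect_lt(abs(mean(draws)), 3 / sqrt(10000))
  expect_equal(sd(draws), 1, tolerance = 0.05)
})

test_that("noiseless runs consume no randomness and seeds give identical draws", {
  set.seed(55); before <- rnorm(1)
  set.seed(55); invisible(simulate_case(1, a = 1, noise = 0)); after <- rnorm(1)
  expect_equal(before, after)
  set.seed(7); d1 <- simulate_case(1, a = 1, noise = 0.5)
  set.seed(7); d2 <- simulate_case(1, a = 1, noise = 0.5)
  expect_equal(d1, d2)
})

test_that("scenario runner aggregates rates, means and table p-values", {
  r <- run_scenario(1, a = 1, noise = 0.5, n_rep = 20, seed = 2)
  expect_equal(r$measure,
               c("kc_poly2", "kc_poly3", "kc_rbf", "pearson", "kendall",
                 "dcor"))
  expect_true(all(r$rate >= 0 & r$rate <= 1))
  expect_equal(r$n_sig, r$rate * 20, ignore_attr = TRUE)
  expect_equal(r$p_value,
               vapply(r$mean, plugin_cor_test, numeric(1), n = 18))
  # identical seed, identical table
  r2 <- run_scenario(1, a = 1, noise = 0.5, n_rep = 20, seed = 2)
  expect_equal(r, r2)
})

test_that("threshold boundaries behave: 0 kills all calls, 0.999 passes most", {
  r0 <- run_scenario(1, a = 1, noise = 0.5, n_rep = 10, threshold = 1e-300,
                     seed = 3)
  expect_true(all(r0$rate[r0$mean < 1] == 0))
  r1 <- run_scenario(1, a = 1, noise = 0.5, n_rep = 10, threshold = 0.999,
                     seed = 3)
  expect_true(all(r1$rate >= r0$rate))
})

test_that("noiseless scenarios are deterministic single computations", {
  r <- run_scenario(2, a = 1, noise = 0, n_rep = 100)
  expect_true(all(is.na(r$rate)))
  expect_equal(attr(r, "scenario")$n_rep, 1L)
  # Case 2 noiseless: G1 is a positive multiple of G2, every measure is 1
  expect_equal(r$mean, rep(1, 6), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("standardized kernelized measures are noise-scale invariant under
           the null", {
  # with z-scoring, the null series c*eps are distribution-invariant in c,
  # so the kc null values coincide draw for draw across c
  set.seed(91); a1 <- simulate_case(1, a = 0, noise = 0.5)
  set.seed(91); a2 <- simulate_case(1, a = 0, noise = 2.0)
  spec <- kernel_spec("rbf", gamma = 0.5, standardize = TRUE)
  expect_equal(kernel_cor(a1$x, a1$y, spec), kernel_cor(a2$x, a2$y, spec))
})

test_that("full table grid has the expected shape and writes TSV", {
  tmp <- tempfile("simtab")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  tabs <- build_sim_tables(seed = 11, n_rep = 5, dir = tmp)
  expect_named(tabs, c("case1", "case2", "case3"))
  for (tab in tabs) {
    expect_equal(nrow(tab), 6)
    expect_true(all(c("fpr_c0.5", "fpr_c1", "fpr_c2", "tpr_c0.5", "tpr_c1",
                      "tpr_c2", "mean_c0", "p_c0") %in% names(tab)))
  }
  files <- list.files(tmp, pattern = "^sim_case[123]\\.tsv$")
  expect_length(files, 3)
  re <- read.delim(file.path(tmp, "sim_case1.tsv"))
  expect_equal(nrow(re), 6)
})
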