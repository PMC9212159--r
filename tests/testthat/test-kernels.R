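test_that("standardization z-scores and rejects constant series", {
  expect_equal(standardize_series(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize_series(c(5, 5, 5)), "constant series")
  t_i <- sim_time_grid()
  z <- standardize_series(2 * sin(t_i * pi / 42) - 0.5)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
})

test_that("pointwise kernels match hand-computed values", {
  expect_equal(polynomial_kernel(c(0, 0), c(3, -7), 2), 1)
  expect_equal(polynomial_kernel(c(1, 1), c(1, 1), 2), 9)
  expect_equal(polynomial_kernel(c(1, -1), c(-1, 1), 3), -1)
  expect_equal(rbf_kernel(c(2.3, -1), c(2.3, -1), 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), 0.5), exp(-1))
  expect_equal(rbf_kernel(c(0, 0), c(0, 10), 0.5), exp(-50))
  expect_error(rbf_kernel(c(0, 0), c(1, 1), -1), "positive")
})

test_that("RBF Gram matrix has unit diagonal and the all-ones degenerate form", {
  p <- random_pair(10, seed = 3)
  g <- gram_matrix(p$x, p$y, kernel_spec("rbf", gamma = 2))
  expect_equal(diag(g$K), rep(1, 10), ignore_attr = TRUE)
  expect_true(isSymmetric(g$K))
  # both series constant, no standardization: all points coincide
  g0 <- gram_matrix(rep(2, 5), rep(-1, 5),
                    kernel_spec("rbf", gamma = 1, standardize = FALSE))
  expect_equal(g0$K, matrix(1, 5, 5), ignore_attr = TRUE)
})

test_that("double-centering matches the H K H definition and kills constants", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(25), 5, 5)
    K <- A + t(A)
    expect_lt(max(abs(double_center(K) - oracle_double_center(K))), 1e-12)
  }
  expect_equal(double_center(matrix(1, 4, 4)), matrix(0, 4, 4))
  expect_error(double_center(matrix(1, 2, 3)), "square")
})

test_that("kernelized vectors sum to zero and inherit pair symmetry", {
  p <- random_pair(15, seed = 7)
  for (spec in list(kernel_spec("rbf", gamma = 0.7),
                    kernel_spec("polynomial", degree = 2))) {
    kp <- kernelize_pair(p$x, p$y, spec)
    expect_lt(abs(sum(kp$xk)), 1e-10)
    expect_lt(abs(sum(kp$yk)), 1e-10)
    expect_lt(max(abs(rowSums(kp$Kc))), 1e-10)
    expect_lt(max(abs(colSums(kp$Kc))), 1e-10)
    # Kc annihilates constant vectors
    expect_lt(max(abs(kp$Kc %*% rep(3.7, 15))), 1e-9)
  }
  kp2 <- kernelize_pair(p$x, p$x, kernel_spec("rbf", gamma = 1))
  expect_equal(kp2$xk, kp2$yk)
})

test_that("kernelized correlation handles exact linear relations", {
  p <- random_pair(12, seed = 11)
  spec <- kernel_spec("rbf", gamma = 0.5)
  expect_equal(kernel_cor(p$x, 2 * p$x + 3, spec), 1)
  expect_equal(kernel_cor(p$x, -p$x, spec), -1)
})

test_that("kernelized correlation is symmetric, bounded, location-invariant,
           and sign-antisymmetric under RBF", {
  for (seed in 1:5) {
    p <- random_pair(14, seed = seed)
    for (spec in list(kernel_spec("rbf", gamma = 0.5),
                      kernel_spec("polynomial", degree = 2),
                      kernel_spec("polynomial", degree = 3))) {
      v <- kernel_cor(p$x, p$y, spec)
      expect_equal(v, kernel_cor(p$y, p$x, spec))
      expect_lte(abs(v), 1)
      expect_equal(kernel_cor(p$x, p$x + 4.2, spec), 1)
    }
    rbf <- kernel_spec("rbf", gamma = 0.8)
    expect_equal(kernel_cor(p$x, -p$y, rbf),
                 -kernel_cor(p$x, p$y, rbf))
  }
})

test_that("large-gamma RBF limit recovers the Pearson correlation", {
  for (seed in 1:3) {
    p <- random_pair(10, seed = 20 + seed)
    spec <- kernel_spec("rbf", gamma = 1e6, standardize = FALSE)
    expect_equal(kernel_cor(p$x, p$y, spec), cor(p$x, p$y),
                 tolerance = 1e-6)
  }
})

test_that("degenerate kernelization is an error, not NaN", {
  # a huge gamma on duplicated points collapses Kc toward a rank-deficient
  # matrix; a constant-x pair does so immediately
  expect_error(
    kernel_cor(rep(1, 5), c(1, 2, 3, 4, 5),
               kernel_spec("rbf", gamma = 0.5, standardize = FALSE)),
    "degenerate")
})
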