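chi_square_inertia <- function(Y) {
  # independent oracle: chi-square statistic of the table / grand total
  E <- outer(rowSums(Y), colSums(Y)) / sum(Y)
  sum((Y - E)^2 / E) / sum(Y)
}

random_table <- function(n, m, seed) {
  withr::with_seed(seed, matrix(rpois(n * m, 8) + 1, n, m))
}

test_that("total inertia equals the chi-square statistic over the grand total", {
  for (seed in 1:10) {
    Y <- random_table(8, 4, seed)
    X <- withr::with_seed(seed + 100, matrix(rnorm(16), 8, 2))
    fit <- cca_fit(Y, X)
    expect_equal(fit$total_inertia, chi_square_inertia(Y), tolerance = 1e-12)
    expect_true(all(diff(fit$eig) <= 1e-12))           # nonincreasing
    expect_true(all(fit$eig >= 0 & fit$eig < 1))
    expect_lte(sum(fit$eig), fit$total_inertia + 1e-10)
    expect_lte(fit$constrained_inertia, fit$total_inertia + 1e-10)
  }
})

test_that("identical site profiles give zero inertia everywhere", {
  Y <- matrix(rep(c(4, 2, 6), each = 6), 6, 3)
  X <- matrix(rnorm(6), 6, 1)
  fit <- cca_fit(Y, X)
  expect_equal(fit$total_inertia, 0, tolerance = 1e-12)
  expect_true(length(fit$eig) == 0 || all(fit$eig < 1e-12))
})

test_that("saturated X reproduces correspondence-analysis eigenvalues", {
  skip_if_not_installed("vegan")
  for (seed in 1:10) {
    Y <- random_table(8, 4, seed + 30)
    # full site-indicator basis (n-1 dummies): projection is the identity
    X <- stats::model.matrix(~ factor(seq_len(8)))[, -1]
    fit <- cca_fit(Y, X)
    ca <- vegan::cca(Y)
    expect_equal(fit$eig[seq_along(ca$CA$eig)], unname(ca$CA$eig),
                 tolerance = 1e-8)
  }
})

test_that("constrained solution agrees with an independent CCA implementation", {
  skip_if_not_installed("vegan")
  for (seed in 1:6) {
    Y <- random_table(12, 5, seed + 60)
    X <- withr::with_seed(seed, matrix(rnorm(36), 12, 3))
    fit <- cca_fit(Y, X)
    vg <- vegan::cca(Y, X)
    expect_equal(fit$eig, unname(vg$CCA$eig), tolerance = 1e-8)
    expect_equal(fit$total_inertia, vg$tot.chi, tolerance = 1e-8)
    expect_equal(fit$constrained_inertia, sum(vg$CCA$eig), tolerance = 1e-8)
  }
})

test_that("an indicator separating two community profiles captures the
           between-group inertia", {
  # 6 x 3 table: two homogeneous blocks of identical rows
  Y <- rbind(matrix(rep(c(10, 2, 1), each = 3), 3, byrow = FALSE),
             matrix(rep(c(1, 5, 9), each = 3), 3, byrow = FALSE))
  Y <- rbind(c(10, 2, 1), c(10, 2, 1), c(10, 2, 1),
             c(1, 5, 9), c(1, 5, 9), c(1, 5, 9))
  X <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1)
  fit <- cca_fit(Y, X)
  # within groups rows are identical, so all inertia is between-group:
  # the indicator explains everything
  expect_equal(fit$constrained_inertia, fit$total_inertia, tolerance = 1e-10)
  expect_equal(fit$residual_inertia, 0, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected or repaired with a warning", {
  Y <- random_table(8, 3, 1)
  Y0 <- cbind(Y, 0)
  expect_warning(fit <- cca_fit(Y0, matrix(rnorm(8), 8, 1)), "all-zero")
  X <- cbind(a = rnorm(8), b = 1:8)
  X2 <- cbind(X, b_copy = X[, 2])
  expect_error(cca_fit(Y, X2), "aliased")
  expect_error(cca_fit(Y[1:3, ], matrix(rnorm(9), 3, 3)), "more sites")
  expect_error(cca_fit(-Y, matrix(rnorm(8))), "nonnegative")
})

test_that("permutation p has the right floor and plants are detected", {
  # minimum attainable p = 1/(n_perm + 1)
  Y <- rbind(c(30, 1, 1), c(28, 2, 1), c(1, 30, 2), c(2, 29, 1),
             c(1, 2, 30), c(2, 1, 28), c(30, 2, 2), c(1, 28, 2))
  X <- matrix(c(1, 1, 0, 0, -1, -1, 1, 0), ncol = 1)
  # X strongly tied to the profile blocks: well below any permutation
  X <- matrix(c(2, 2, 0, 0, -2, -2, 2, 0) + rnorm(8, 0, 0.01), ncol = 1)
  out <- cca_permutation_test(Y, X, n_perm = 99, seed = 5)
  expect_gte(out$p_value, 1 / 100)
  expect_lte(out$p_value, 1)
  # reproducible under the same seed
  out2 <- cca_permutation_test(Y, X, n_perm = 99, seed = 5)
  expect_identical(out$p_value, out2$p_value)
})

test_that("forward selection skips duplicates and rejects pure noise", {
  withr::with_seed(11, {
    n <- 80
    x1 <- rnorm(n)
    lam <- exp(1.5 + 1.2 * x1)
    Y <- cbind(rpois(n, lam), rpois(n, 5), rpois(n, exp(1 + 0.8 * x1))) + 1
    X <- tibble::tibble(signal = x1, dup = x1, noise = rnorm(n))
  })
  sel <- aic_forward_select(Y, X, n_perm = 99, seed = 2)
  expect_true("signal" %in% sel$selected)
  expect_false("dup" %in% sel$selected)  # zero marginal inertia after signal

  withr::with_seed(12, {
    Yn <- matrix(rpois(80 * 3, 10), 80, 3) + 1
    Xn <- tibble::tibble(noise = rnorm(80))
  })
  seln <- aic_forward_select(Yn, Xn, n_perm = 0, seed = 3)
  expect_length(seln$selected, 0)  # intercept-only beats one noise column
})
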