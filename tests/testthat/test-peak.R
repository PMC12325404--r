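test_that("quadratic regression recovers exact parabolas and matches normal equations", {
  x <- seq(0.05, 0.95, length.out = 10)
  items <- items_from_parabola(x, b0 = -0.15, b1 = 1, b2 = -1)  # peak at 0.5
  co <- quadratic_fit(items)
  expect_equal(co, c(b0 = -0.15, b1 = 1, b2 = -1), tolerance = 1e-10)
  expect_equal(peak_location(co), 0.5, tolerance = 1e-10)

  # linear-algebra oracle on noisy data: solve the normal equations directly
  set.seed(41)
  xr <- runif(25); yr <- 0.1 + 0.4 * xr - 0.6 * xr^2 + rnorm(25, 0, 0.05)
  noisy <- items_from_parabola(xr, 0, 0, 0)
  noisy$truth_effect <- yr
  co2 <- quadratic_fit(noisy)
  X <- cbind(1, xr, xr^2)
  beta <- solve(t(X) %*% X, t(X) %*% yr)
  expect_equal(unname(co2), as.numeric(beta), tolerance = 1e-10)

  expect_error(quadratic_fit(items[1:2, ]), "at least 3")
  flat <- items_from_parabola(rep(0.4, 5), 0, 0, 0)
  expect_error(quadratic_fit(flat), "Rank-deficient")
})

test_that("peak location handles trivial and degenerate coefficients", {
  expect_equal(peak_location(c(b1 = 1, b2 = -1)), 0.5)
  expect_equal(peak_location(c(b1 = 0, b2 = -2)), 0)
  expect_true(is.na(peak_location(c(b1 = 1, b2 = 0))))
  expect_true(is.na(peak_location(c(b1 = 1, b2 = 2))))
})

test_that("symmetric noiseless constant-shift data peak at one half", {
  # sample the M1 curve on a grid symmetric around its center of symmetry
  # (p = 0.5 - m/2): perceived-truth pairs then mirror around .5 exactly
  m <- 0.4
  p <- (0.5 - m / 2) + seq(-1.3, 1.3, by = 0.05)
  items <- items_from_curve("M1", m, p = p)
  co <- quadratic_fit(items, x_mode = "mean_RN")
  expect_equal(peak_location(co), 0.5, tolerance = 1e-8)
  # on the default asymmetric grid the fitted peak is still close to .5
  co2 <- quadratic_fit(items_from_curve("M1", m))
  expect_lt(abs(peak_location(co2) - 0.5), 0.01)
})

test_that("the bootstrap CI collapses on noiseless peaked data and rejects off-center peaks", {
  x <- seq(0.2, 0.95, length.out = 30)
  items <- items_from_parabola(x, b0 = -0.39, b1 = 1.4, b2 = -1)  # peak at 0.7
  set.seed(91)
  res <- bootstrap_peak_ci(items, n_bootstrap = 400)
  expect_equal(res$peak, 0.7, tolerance = 1e-8)
  expect_lt(res$ci_hi - res$ci_lo, 1e-6)
  expect_true(res$reject)
  expect_equal(res$n_degenerate, 0)
  expect_s3_class(tidy(res), "tbl_df")

  # reproducibility under a fixed seed
  set.seed(91)
  res2 <- bootstrap_peak_ci(items, n_bootstrap = 400)
  expect_equal(res$ci_lo, res2$ci_lo)
  expect_equal(res$ci_hi, res2$ci_hi)
})

test_that("upward-opening data yield the flagged no-peak outcome", {
  x <- seq(0.1, 0.9, length.out = 20)
  items <- items_from_parabola(x, b0 = 0.3, b1 = -1, b2 = 1)
  set.seed(13)
  expect_warning(res <- bootstrap_peak_ci(items, n_bootstrap = 200),
                 "unreliable")
  expect_false(res$reliable)
  expect_false(res$reject)
  expect_equal(res$n_degenerate, 200)
  expect_true(is.na(res$peak))
})

test_that("x_mode new_only uses the pre-manipulation proportions", {
  items <- items_from_curve("M3", 0.4)
  co_mean <- quadratic_fit(items, "mean_RN")
  co_new <- quadratic_fit(items, "new_only")
  # under M3 the effect is largest for implausible items: both peaks sit
  # below .5, and the new-only peak is not the same number
  expect_lt(peak_location(co_new), 0.5)
  expect_false(isTRUE(all.equal(peak_location(co_mean), peak_location(co_new))))
})

test_that("the midpoint test has near-nominal size under the null and full power under M2/M3", {
  set.seed(23)
  null_power <- power_study("M1", 0, n_datasets = 150, n_bootstrap = 1000)
  expect_lt(null_power$rejection_rate, 0.12)

  set.seed(24)
  p2 <- power_study("M2", 0.4, n_datasets = 40, n_bootstrap = 1000)
  expect_equal(p2$rejection_rate, 1)
  set.seed(25)
  p3 <- power_study("M3", 0.4, n_datasets = 40, n_bootstrap = 1000)
  expect_equal(p3$rejection_rate, 1)
  expect_s3_class(tidy(p2), "tbl_df")
})

test_that("rejection rates order as M1 < M4 << M2/M3 at moderate shift", {
  set.seed(26)
  r1 <- power_study("M1", 0.2, n_datasets = 150, n_bootstrap = 1000)$rejection_rate
  r4 <- power_study("M4", 0.2, n_datasets = 150, n_bootstrap = 1000)$rejection_rate
  r2 <- power_study("M2", 0.2, n_datasets = 40, n_bootstrap = 1000)$rejection_rate
  expect_lt(r1, r4)
  expect_lt(r4, r2)
  expect_equal(r2, 1)
})

test_that("power studies reproduce under a fixed seed", {
  set.seed(77)
  a <- power_study("M4", 0.2, n_datasets = 20, n_bootstrap = 500)
  set.seed(77)
  b <- power_study("M4", 0.2, n_datasets = 20, n_bootstrap = 500)
  expect_identical(a$rejects, b$rejects)
})
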