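test_that("prob_true_new matches the normal-CDF integral and is symmetric", {
  expect_equal(prob_true_new(0.5), 0.5)
  # independent oracle: numerical integration of the standard normal density
  phi1 <- integrate(dnorm, -Inf, 1)$value
  expect_equal(prob_true_new(1.0), phi1, tolerance = 1e-8)
  eps <- 0.3
  expect_equal(prob_true_new(0.5 + eps) - 0.5, 0.5 - prob_true_new(0.5 - eps),
               tolerance = 1e-12)
  expect_true(all(diff(prob_true_new(seq(-1, 2, by = 0.01))) > 0))
  expect_error(prob_true_new(NaN), "finite")
  expect_error(link_spec(sigma = -1), "positive")
})

test_that("fluency shifts follow the four variant formulas, literally outside [0,1]", {
  expect_equal(fluency_shift("M1", 0.1, -0.7), 0.1)
  expect_equal(fluency_shift("M3", 0.3, 1), 0)
  expect_equal(fluency_shift("M4", 0.4, 0.5), 0.4)
  # literal application below p = 0 / above p = 1 gives negative shifts
  expect_lt(fluency_shift("M2", 0.2, -0.5), 0)
  expect_lt(fluency_shift("M3", 0.2, 1.5), 0)
  expect_lt(fluency_shift("M4", 0.2, 2), 0)
  expect_error(fluency_shift("M5", 0.1, 0), "variant")
  expect_error(fluency_shift("M1", -0.1, 0))
})

test_that("prob_true_rep reduces to the new-statement curve at m = 0", {
  for (v in model_variants()) {
    expect_equal(prob_true_rep(v, 0.5, 0), 0.5)
    p <- seq(-1, 2, by = 0.25)
    expect_equal(prob_true_rep(v, p, 0), prob_true_new(p), tolerance = 1e-15)
  }
  phi08 <- integrate(dnorm, -Inf, 0.8)$value
  expect_equal(prob_true_rep("M1", 0.5, 0.4), phi08, tolerance = 1e-8)
  expect_lt(prob_true_rep("M2", -0.5, 0.2), prob_true_new(-0.5))
})

test_that("truth-effect curves satisfy their defining identities", {
  curve <- truth_effect_curve("M1", 0.4)
  expect_equal(nrow(curve), 301)
  expect_equal(curve$truth_effect, curve$theta_rep - curve$theta_new)
  expect_equal(curve$perceived_truth_mean, (curve$theta_rep + curve$theta_new) / 2)
  expect_equal(curve$perceived_truth_N, curve$theta_new)
  # the repetition effect on the probability scale diminishes at the extremes
  mid <- curve$truth_effect[curve$p == 0.5]
  expect_gt(mid, curve$truth_effect[curve$p == -1])
  expect_gt(mid, curve$truth_effect[curve$p == 2])
  for (v in model_variants()) {
    expect_true(all(truth_effect_curve(v, 0)$truth_effect == 0))
  }
})

test_that("M1 peak truth effect matches a dense-grid brute-force search", {
  # oracle: exhaustive search on a 100x finer grid
  dense <- seq(-1, 2, by = 1e-4)
  brute <- max(pnorm((dense + 0.1 - 0.5) / 0.5) - pnorm((dense - 0.5) / 0.5))
  curve <- truth_effect_curve("M1", 0.1)
  expect_equal(max(curve$truth_effect), brute, tolerance = 1e-5)
  # for M1 the maximum straddles the point where the two probit args bracket 0
  at_max <- curve$p[which.max(curve$truth_effect)]
  expect_true(at_max >= 0.5 - 0.1 - 0.01 && at_max <= 0.5 + 0.01)
})

test_that("probit-scale additivity holds exactly under M1", {
  sigma <- 0.5
  for (m in c(0.1, 0.2, 0.4)) {
    curve <- truth_effect_curve("M1", m)
    gap <- qnorm(curve$theta_rep) - qnorm(curve$theta_new)
    expect_true(all(abs(gap - m / sigma) < 1e-10))
  }
})

test_that("sign of the truth effect follows the variant-specific regions", {
  p <- seq(-1, 2, by = 0.05)
  m <- 0.3
  eff <- function(v) prob_true_rep(v, p, m) - prob_true_new(p)
  expect_true(all(eff("M1") >= 0))
  expect_true(all((eff("M2") >= 0) == (p >= 0)))
  expect_true(all((eff("M3") >= 0) == (p <= 1)))
  expect_true(all((eff("M4") >= -1e-15) == (p >= 0 & p <= 1) |
                    abs(eff("M4")) < 1e-15))
})

test_that("theta_rep is nondecreasing in m for fixed p in (0,1)", {
  ms <- seq(0, 0.5, by = 0.05)
  for (v in model_variants()) {
    for (p in c(0.1, 0.5, 0.9)) {
      vals <- sapply(ms, function(m) prob_true_rep(v, p, m))
      expect_true(all(diff(vals) >= -1e-15), label = paste(v, "p =", p))
    }
  }
})

test_that("curve shapes for the printed m values match the expected skews", {
  for (m in c(0.1, 0.2, 0.4)) {
    argmax_x <- function(v) {
      curve <- truth_effect_curve(v, m)
      curve$perceived_truth_mean[which.max(curve$truth_effect)]
    }
    argmax_p <- function(v) {
      curve <- truth_effect_curve(v, m)
      curve$p[which.max(curve$truth_effect)]
    }
    # constant shift: inverted U centered exactly at perceived truth .5
    expect_lt(abs(argmax_x("M1") - 0.5), 0.01)
    # triangular shift peaks at plausibility .5, which maps to a perceived
    # truth slightly above .5 (the repeated proportion is already shifted)
    expect_lt(abs(argmax_p("M4") - 0.5), 0.01)
    expect_gt(argmax_x("M4"), 0.5)
    expect_lt(argmax_x("M4"), 0.5 + m / 2 + 0.01)
    expect_gt(argmax_x("M2"), 0.52)                   # right-skewed
    expect_lt(argmax_x("M3"), 0.48)                   # left-skewed
  }
})

test_that("scale transforms invert each other and change the interaction", {
  expect_equal(transform_scale(0.5, "probit"), 0)
  expect_equal(transform_scale(0.5, "logit"), 0)
  expect_equal(transform_scale(0.73, "probability"), 0.73)
  theta <- c(0.01, 0.3, 0.5, 0.9, 0.999)
  expect_equal(pnorm(transform_scale(theta, "probit")), theta, tolerance = 1e-12)
  expect_equal(plogis(transform_scale(theta, "logit")), theta, tolerance = 1e-12)
  expect_error(transform_scale(0, "probit"), "strictly")
  expect_error(transform_scale(1, "logit"), "strictly")
  # equal probit gaps near zero vs far out give unequal probability gaps
  expect_gt(pnorm(1.00) - pnorm(0.60), pnorm(2.14) - pnorm(1.74))
})

test_that("curve export columns round-trip through CSV", {
  curve <- truth_effect_curve("M2", 0.2, seq(-1, 2, by = 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(curve, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("p", "theta_new", "theta_rep", "truth_effect",
                              "perceived_truth_N", "perceived_truth_mean"))
  expect_equal(back$truth_effect, curve$truth_effect, tolerance = 1e-12)
})

test_that("curve and item plots build without error", {
  expect_s3_class(plot_truth_effect_curves(m = 0.2), "ggplot")
  items <- items_from_curve("M1", 0.2)
  expect_s3_class(plot_item_effects(items, curve = truth_effect_curve("M1", 0.2)),
                  "ggplot")
})
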