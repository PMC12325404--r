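test_that("pointwise log-likelihood equals the closed-form Bernoulli-probit expression", {
  trials <- tibble::tibble(
    participant_id = c(1, 1, 2, 2, 2),
    statement_id = c(1, 2, 1, 2, 3),
    repeated = c(0, 1, 1, 0, 1),
    judgment = c(1, 0, 1, 1, 0)
  )
  p <- c(0.2, 0.8, -0.3); v <- c(0.05, -0.02, 0.1); u <- c(0.1, -0.15)
  m <- 0.25
  draws <- matrix(c(m, 0.5, 0.7, 0.3, 0.1, p, u, v), nrow = 1)
  colnames(draws) <- c("m", "mu_p", "sigma_p", "sigma_u", "sigma_v",
                       "p[1]", "p[2]", "p[3]", "u[1]", "u[2]",
                       "v[1]", "v[2]", "v[3]")
  for (variant in model_variants()) {
    fake <- structure(list(
      variant = variant, link = link_spec(), trials = trials,
      statement_levels = 1:3, participant_levels = 1:2,
      item = trials$statement_id, subj = trials$participant_id,
      prior_only = FALSE
    ), class = "truth_fit")
    ll <- pointwise_loglik(fake, draws)
    f <- fluency_shift(variant, m, p)
    eta <- p[trials$statement_id] +
      trials$repeated * (f[trials$statement_id] + v[trials$statement_id]) +
      u[trials$participant_id]
    theta <- pnorm((eta - 0.5) / 0.5)
    manual <- trials$judgment * log(theta) + (1 - trials$judgment) * log(1 - theta)
    expect_equal(as.numeric(ll), manual, tolerance = 1e-10)
  }
})

test_that("a prior-only fit reproduces its prior within Monte Carlo error", {
  fit <- fit_truth_model(
    tibble::tibble(participant_id = integer(), statement_id = integer(),
                   repeated = integer(), judgment = integer()),
    "M2", settings = mcmc_settings_desk(chains = 2, draws = 20000, seed = 4)
  )
  expect_true(fit$prior_only)
  m <- fit$draws[, "m"]
  # truncated-normal moments for N+(0.27, 0.1): computed from closed form
  mm <- 0.27; sm <- 0.1
  a <- -mm / sm
  tn_mean <- mm + sm * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(m) - tn_mean), 4 * sd(m) / sqrt(coda::effectiveSize(coda::mcmc(m))))
  expect_true(all(m > 0))
  expect_lt(abs(mean(fit$draws[, "mu_p"]) - 0.5), 0.02)
})

test_that("split R-hat separates healthy from pathological chains", {
  set.seed(8)
  good <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  dg <- diagnostics(good, chain_id = rep(1:4, each = 500))
  expect_true(all(dg$rhat < 1.01))
  expect_true(all(dg$ess > 1000))

  stuck <- cbind(x = c(rep(0, 500), rep(5, 500)))
  ds <- diagnostics(stuck, chain_id = rep(1:2, each = 500))
  expect_true(!is.finite(ds$rhat) || ds$rhat > 2)
  expect_error(diagnostics(good), "chain_id")
})

test_that("HDI behaves on symmetric, skewed and degenerate draws", {
  set.seed(9)
  x <- rnorm(50000)
  h <- hdi(x)
  expect_equal(h, quantile(x, c(0.025, 0.975), names = FALSE), tolerance = 0.05)
  expect_equal(hdi(rep(3, 100)), c(3, 3))
  ex <- rexp(50000)
  he <- hdi(ex)
  expect_lt(he[1], 0.01)  # shortest interval hugs zero for a decaying density
})

test_that("posterior summary reports hyper-parameters and realized variances", {
  d <- design_spec(8, 12)
  set.seed(21)
  trials <- simulate_trials(d, draw_parameters(d, "M1", 0.2))
  fit <- cached("fit_small_m1", quiet_fit(trials, "M1", chains = 2,
                                          warmup = 200, draws = 400, seed = 2))
  s <- posterior_summary(fit)
  expect_true(all(c("m", "mu_p", "sigma_p", "sigma_u", "sigma_v",
                    "var(u)", "var(v)", "sigma_u^2") %in% s$parameter))
  expect_true(all(s$hdi_lo <= s$mean & s$mean <= s$hdi_hi))
  expect_true(all(s$sd >= 0))
  td <- tidy(fit)
  expect_identical(td, s)
  g <- glance(fit)
  expect_equal(g$n_trials, 96L)
  expect_equal(g$n_draws, 800L)
  expect_s3_class(autoplot(fit, n_draws = 20), "ggplot")
})

test_that("a zero participant-variance truth concentrates sigma_u near zero", {
  d <- design_spec(20, 60, sigma_u = 0, sigma_v = 0)
  set.seed(33)
  trials <- simulate_trials(d, draw_parameters(d, "M1", 0.2))
  fit <- cached("fit_sigma_u0", quiet_fit(trials, "M1", chains = 2,
                                          warmup = 500, draws = 1200, seed = 6))
  expect_lt(hdi(fit$draws[, "sigma_u"])[1], 0.05)
})

test_that("prior-predictive average truth effects stay in a plausible band", {
  set.seed(12)
  for (variant in model_variants()) {
    pr <- prior_spec(variant)
    # positive-truncated normal prior draws via inverse CDF
    lo <- pnorm(0, pr$m_mean, pr$m_sd)
    m_draws <- qnorm(lo + runif(40) * (1 - lo), pr$m_mean, pr$m_sd)
    effects <- sapply(m_draws, function(m)
      implied_truth_effect(variant, m, analytic = TRUE))
    expect_true(all(effects >= -1e-9 & effects < 0.2),
                label = paste("prior-predictive band for", variant))
    expect_gt(mean(effects > 0 & effects < 0.15), 0.9)
  }
})

test_that("the Gibbs engine and JAGS agree on the posterior of m", {
  set.seed(19)
  d <- design_spec(14, 28)
  trials <- simulate_trials(d, draw_parameters(d, "M2", 0.4))
  fg <- quiet_fit(trials, "M2", chains = 2, warmup = 500, draws = 2000, seed = 5)
  fj <- suppressWarnings(fit_truth_model(trials, "M2", engine = "jags",
    settings = mcmc_settings_desk(chains = 2, warmup = 400, draws = 1200,
                                  seed = 5)))
  for (par in c("m", "mu_p", "sigma_u")) {
    mg <- mean(fg$draws[, par]); mj <- mean(fj$draws[, par])
    pooled_sd <- sqrt((sd(fg$draws[, par])^2 + sd(fj$draws[, par])^2) / 2)
    expect_lt(abs(mg - mj), 0.5 * pooled_sd, label = paste("engine gap for", par))
  }
})

test_that("mismatched priors and variants are refused", {
  trials <- make_fixtures(1)$toy
  expect_error(fit_truth_model(trials, "M1", priors = prior_spec("M2")),
               "variant")
})
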