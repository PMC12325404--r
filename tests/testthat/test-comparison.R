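test_that("bridge sampling recovers the conjugate Beta-Bernoulli log marginal", {
  n <- 20; k <- 13
  exact <- lbeta(1 + k, 1 + n - k) - lbeta(1, 1)
  log_post <- function(z) {
    th <- plogis(z[, 1])
    k * log(th) + (n - k) * log1p(-th) + log(th) + log1p(-th)  # + logit Jacobian
  }
  set.seed(501)
  theta <- rbeta(8000, 1 + k, 1 + n - k)
  b <- bridge_sampler_core(cbind(qlogis(theta)), log_post, seed = 601)
  expect_true(b$converged)
  expect_lt(abs(b$logml - exact), 0.01)

  # unbiasedness across 20 replicate posteriors
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    th <- rbeta(6000, 1 + k, 1 + n - k)
    bridge_sampler_core(cbind(qlogis(th)), log_post, seed = s + 1000)$logml - exact
  })
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("bridge estimates of one fit agree across proposal seeds", {
  d <- design_spec(8, 12)
  set.seed(21)
  trials <- simulate_trials(d, draw_parameters(d, "M1", 0.2))
  fit <- cached("fit_small_m1", quiet_fit(trials, "M1", chains = 2,
                                          warmup = 200, draws = 400, seed = 2))
  b1 <- log_marginal_likelihood(fit, seed = 11)
  b2 <- log_marginal_likelihood(fit, seed = 22)
  expect_lt(abs(b1$logml - b2$logml),
            3 * sqrt(b1$mc_error^2 + b2$mc_error^2) + 1e-6)
})

test_that("a prior-only fit has log marginal likelihood exactly zero", {
  empty <- tibble::tibble(participant_id = integer(), statement_id = integer(),
                          repeated = integer(), judgment = integer())
  fit <- fit_truth_model(empty, "M3")
  expect_identical(log_marginal_likelihood(fit)$logml, 0)
})

test_that("Bayes factors and posterior model probabilities follow their algebra", {
  expect_equal(bayes_factor(-5, -5), 1)
  expect_equal(bayes_factor(-5 + log(10), -5), 10)
  expect_equal(bayes_factor(-3, -7) * bayes_factor(-7, -3), 1)
  expect_equal(bayes_factor(-3, -7, log = TRUE), 4)

  expect_equal(posterior_model_probs(c(-10, -10, -10, -10)), rep(0.25, 4),
               ignore_attr = TRUE)
  dom <- posterior_model_probs(c(0, -50))
  expect_gt(dom[1], 1 - 1e-15)
  lmls <- c(M1 = -100, M2 = -103, M3 = -110, M4 = -104)
  # direct normalization oracle
  direct <- exp(lmls - max(lmls)); direct <- direct / sum(direct)
  expect_equal(posterior_model_probs(lmls), direct, tolerance = 1e-12)
  expect_equal(sum(posterior_model_probs(lmls)), 1, tolerance = 1e-12)
  expect_error(posterior_model_probs(lmls, prior_probs = c(0.5, 0.5)), "simplex")
  # huge separations stay finite on the log scale
  expect_equal(posterior_model_probs(c(-1e6, -1e6 - 5))[1], plogis(5),
               ignore_attr = TRUE)
})

test_that("PSIS-LOO handles trivial cases and matches brute-force refits", {
  # likelihood identically one: elpd is zero
  flat <- matrix(0, 200, 10)
  l0 <- loo_elpd(flat)
  expect_equal(l0$elpd, 0)

  # identical fits have zero ELPD difference
  d <- design_spec(8, 12)
  set.seed(21)
  trials <- simulate_trials(d, draw_parameters(d, "M1", 0.2))
  fit <- cached("fit_small_m1", quiet_fit(trials, "M1", chains = 2,
                                          warmup = 200, draws = 400, seed = 2))
  la <- loo_elpd(fit); lb <- loo_elpd(fit)
  dd <- elpd_diff(la, lb)
  expect_equal(dd$elpd_diff, 0)
  expect_equal(dd$se_diff, 0)

  # brute-force oracle: refit without each trial, score the held-out trial
  d2 <- design_spec(10, 5, sigma_u = 0.2, sigma_v = 0.05)
  set.seed(55)
  small <- simulate_trials(d2, draw_parameters(d2, "M1", 0.3))
  full <- quiet_fit(small, "M1", chains = 2, warmup = 400, draws = 1500, seed = 3)
  psis <- loo_elpd(full)
  brute <- vapply(seq_len(nrow(small)), function(i) {
    refit <- quiet_fit(small[-i, ], "M1", chains = 2, warmup = 400,
                       draws = 1500, seed = 3)
    held <- structure(list(
      variant = "M1", link = refit$link, trials = small[i, ],
      statement_levels = refit$statement_levels,
      participant_levels = refit$participant_levels,
      item = match(small$statement_id[i], refit$statement_levels),
      subj = match(small$participant_id[i], refit$participant_levels),
      prior_only = FALSE
    ), class = "truth_fit")
    ll <- pointwise_loglik(held, refit$draws)
    log(mean(exp(ll)))
  }, 0)
  # total ELPD agreement within the combined standard errors of the two
  # estimates, plus tight pointwise correlation
  se_brute <- sd(brute) * sqrt(length(brute))
  expect_lt(abs(psis$elpd - sum(brute)), sqrt(psis$se^2 + se_brute^2))
  expect_gt(cor(psis$pointwise, brute), 0.95)
})

test_that("model comparison prefers the generating variant and aligns lml with ELPD", {
  d <- design_spec(16, 40, sigma_u = 0.1, sigma_v = 0.05)
  set.seed(61)
  trials <- simulate_trials(d, draw_parameters(d, "M3", 0.5))
  fits <- cached("fits_m3_pair", list(
    M2 = quiet_fit(trials, "M2", chains = 2, warmup = 300, draws = 700, seed = 8),
    M3 = quiet_fit(trials, "M3", chains = 2, warmup = 300, draws = 700, seed = 8)
  ))
  cmp <- compare_models(fits, method = "both", seed = 17)
  expect_equal(sum(cmp$post_prob$probability), 1, tolerance = 1e-12)
  expect_equal(cmp$bf["M3", "M2"], exp(cmp$lml$lml[2] - cmp$lml$lml[1]),
               tolerance = 1e-12)
  expect_equal(cmp$post_prob$variant[which.max(cmp$post_prob$probability)], "M3")
  # rank order by lml and by ELPD agree when models are well separated
  sep <- abs(cmp$elpd_diffs$elpd_diff[cmp$elpd_diffs$variant == "M2"]) >
    2 * cmp$elpd_diffs$se_diff[cmp$elpd_diffs$variant == "M2"]
  if (isTRUE(sep)) {
    expect_equal(order(cmp$lml$lml), order(cmp$elpd$elpd))
  }
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_error(compare_models(list(fits$M2), method = "bridge"))
})
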