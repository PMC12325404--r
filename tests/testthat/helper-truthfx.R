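# Shared helpers for the test suite. Fits used by several tests are cached in
# an environment so each is computed once per test run.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# A small fit; convergence warnings are expected at this scale and silenced.
quiet_fit <- function(trials, variant, chains = 2, warmup = 300, draws = 700,
                      seed = 1, ...) {
  suppressWarnings(fit_truth_model(
    trials, variant,
    settings = mcmc_settings_desk(chains = chains, warmup = warmup,
                                  draws = draws, seed = seed),
    ...
  ))
}

# Noiseless item summaries sampled from an analytic truth-effect curve.
items_from_curve <- function(variant, m, p = seq(-1, 2, length.out = 41)) {
  curve <- truth_effect_curve(variant, m, p)
  tibble::tibble(
    statement_id = seq_along(p),
    prop_new = curve$theta_new,
    prop_rep = curve$theta_rep,
    truth_effect = curve$truth_effect,
    perceived_truth_mean = curve$perceived_truth_mean,
    n_new = 1000L, n_rep = 1000L,
    complete = TRUE
  )
}

# Item summaries lying exactly on y = b0 + b1 x + b2 x^2.
items_from_parabola <- function(x, b0, b1, b2) {
  y <- b0 + b1 * x + b2 * x^2
  tibble::tibble(
    statement_id = seq_along(x),
    prop_new = x, prop_rep = x + y,
    truth_effect = y,
    perceived_truth_mean = x,
    n_new = 100L, n_rep = 100L,
    complete = TRUE
  )
}
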