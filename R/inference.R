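matched_m_means <- c(M1 = 0.11, M2 = 0.27, M3 = 0.19, M4 = 0.38)

#' Prior specification for the hierarchical truth-effect model
#'
#' Hyper-priors of the Bayesian model: `mu_p ~ Normal(0.5, 1)` (implying a
#' roughly uniform prior on the probability scale once the 0.5 threshold is
#' subtracted), half-normal(1) priors for `sigma_p`, `sigma_u`, `sigma_v`,
#' and a positive-truncated normal prior for the fluency magnitude `m`. The
#' default mean of the `m` prior is variant-specific (0.11, 0.27, 0.19, 0.38
#' for M1-M4): these values are scaled so that all four variants imply
#' approximately the same average truth effect of .04 (see
#' [scale_prior_means()]), which keeps the model comparison fair.
#'
#' @param variant Model variant (sets the default `m_mean`).
#' @param m_mean Mean of the truncated-normal prior for `m`; `NULL` uses the
#'   variant's matched value.
#' @param m_sd Sd of the `m` prior (default 0.1).
#' @param mu_p_mean,mu_p_sd Normal prior for the average plausibility.
#' @param sigma_p_sd,sigma_u_sd,sigma_v_sd Scales of the half-normal priors
#'   for the random-effect sds.
#' @return A `prior_spec` object (list).
#' @examples
#' prior_spec("M2")
#' prior_spec("M1", m_mean = 0.1, m_sd = 0.05) # a model-invariant prior
#' @export
prior_spec <- function(variant, m_mean = NULL, m_sd = 0.1,
                       mu_p_mean = 0.5, mu_p_sd = 1,
                       sigma_p_sd = 1, sigma_u_sd = 1, sigma_v_sd = 1) {
  variant <- as_variant(variant)
  if (is.null(m_mean)) m_mean <- matched_m_means[[variant]]
  stopifnot(m_sd > 0, mu_p_sd > 0, sigma_p_sd > 0, sigma_u_sd > 0, sigma_v_sd > 0)
  structure(list(
    variant = variant, m_mean = m_mean, m_sd = m_sd,
    mu_p_mean = mu_p_mean, mu_p_sd = mu_p_sd,
    sigma_p_sd = sigma_p_sd, sigma_u_sd = sigma_u_sd, sigma_v_sd = sigma_v_sd
  ), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> %s: m ~ N+(%g, %g); mu_p ~ N(%g, %g); sigmas ~ half-N(%g, %g, %g)\n",
              x$variant, x$m_mean, x$m_sd, x$mu_p_mean, x$mu_p_sd,
              x$sigma_p_sd, x$sigma_u_sd, x$sigma_v_sd))
  invisible(x)
}

#' MCMC settings
#'
#' The full-scale profile (8 chains, 1,000 warmup iterations, 10,000 retained
#' draws per chain) is the default; [mcmc_settings_desk()] gives a reduced
#' profile suitable for quick desk-scale runs and tests.
#'
#' @param chains,warmup,draws Positive integers.
#' @param seed Integer seed (one RNG stream per chain is derived from it).
#' @return An `mcmc_settings` object (list).
#' @export
mcmc_settings <- function(chains = 8, warmup = 1000, draws = 10000, seed = 1L) {
  stopifnot(chains >= 1, warmup >= 1, draws >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
mcmc_settings_desk <- function(chains = 4, warmup = 500, draws = 1500, seed = 1L) {
  mcmc_settings(chains, warmup, draws, seed)
}

jags_fluency_expr <- function(variant) {
  switch(variant,
    M1 = "m",
    M2 = "m * p[item[n]]",
    M3 = "m * (1 - p[item[n]])",
    M4 = "2 * m * (0.5 - abs(p[item[n]] - 0.5))"
  )
}

jags_model_string <- function(variant, priors, link) {
  sprintf("
model {
  for (n in 1:N) {
    eta[n] <- p[item[n]] + R[n] * (%s + v[item[n]]) + u[subj[n]]
    prob[n] <- max(1e-9, min(1 - 1e-9, phi((eta[n] - %.17g) / %.17g)))
    y[n] ~ dbern(prob[n])
  }
  for (i in 1:S) {
    p[i] ~ dnorm(mu_p, 1 / (sigma_p * sigma_p))
    v[i] ~ dnorm(0, 1 / (sigma_v * sigma_v))
  }
  for (j in 1:P) {
    u[j] ~ dnorm(0, 1 / (sigma_u * sigma_u))
  }
  mu_p ~ dnorm(%.17g, %.17g)
  sigma_p ~ dnorm(0, %.17g) T(0,)
  sigma_u ~ dnorm(0, %.17g) T(0,)
  sigma_v ~ dnorm(0, %.17g) T(0,)
  m ~ dnorm(%.17g, %.17g) T(0,)
}",
    jags_fluency_expr(variant), link$threshold, link$sigma,
    priors$mu_p_mean, 1 / priors$mu_p_sd^2,
    1 / priors$sigma_p_sd^2, 1 / priors$sigma_u_sd^2, 1 / priors$sigma_v_sd^2,
    priors$m_mean, 1 / priors$m_sd^2)
}

rtruncnorm_pos <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

prior_only_fit <- function(variant, priors, settings, link) {
  n_total <- settings$chains * settings$draws
  set.seed(settings$seed)
  draws <- cbind(
    m = rtruncnorm_pos(n_total, priors$m_mean, priors$m_sd),
    mu_p = rnorm(n_total, priors$mu_p_mean, priors$mu_p_sd),
    sigma_p = abs(rnorm(n_total, 0, priors$sigma_p_sd)),
    sigma_u = abs(rnorm(n_total, 0, priors$sigma_u_sd)),
    sigma_v = abs(rnorm(n_total, 0, priors$sigma_v_sd))
  )
  structure(list(
    variant = variant, priors = priors, settings = settings, link = link,
    draws = draws, chain_id = rep(seq_len(settings$chains), each = settings$draws),
    trials = tibble::tibble(participant_id = integer(), statement_id = integer(),
                            repeated = integer(), judgment = integer()),
    statement_levels = character(), participant_levels = character(),
    item = integer(), subj = integer(),
    prior_only = TRUE, converged = TRUE,
    data_fingerprint = "prior-only"
  ), class = "truth_fit")
}

#' Fit a truth-effect model variant to trial-level data
#'
#' Hierarchical Bayesian estimation of one of the four model variants.
#' Each judgment is Bernoulli with success probability
#' `pnorm((p_i + R_ij * (f_i + v_i) + u_j - threshold) / sigma)` where `f_i`
#' is the variant-specific fluency shift; statement plausibilities are
#' modeled hierarchically as `Normal(mu_p, sigma_p)`, and `u_j`, `v_i` are
#' participant and item random effects with half-normal priors on their sds.
#'
#' Two samplers are available. The default (`engine = "gibbs"`) is a blocked
#' data-augmentation Gibbs sampler written for exactly this model family:
#' augmenting each trial with its latent truth value turns the probit
#' likelihood into a linear-Gaussian one, giving exact conjugate updates for
#' the plausibilities, both random-effect vectors, the hyper-mean and the
#' (zero-truncated) fluency magnitude, with adaptive Metropolis steps only
#' for the three scale parameters and for `p` under M4. `engine = "jags"`
#' hands the identical model to JAGS; the two engines are interchangeable
#' and agreement between them is part of the test suite.
#'
#' Passing a zero-row trial table gives a prior-only fit: the "posterior"
#' equals the prior, which is useful for prior-predictive checks and as a
#' base case for marginal likelihoods.
#'
#' @param trials A trial table (see [validate_trials()]).
#' @param variant Model variant.
#' @param priors A [prior_spec()]; defaults to the variant's matched prior.
#' @param settings An [mcmc_settings()]; default is the desk-scale profile.
#' @param link A [link_spec()].
#' @param engine `"gibbs"` (default) or `"jags"`.
#' @param quiet Suppress JAGS progress output (JAGS engine only).
#' @return A `truth_fit` object holding the stacked posterior draws (matrix
#'   with columns `m`, `mu_p`, `sigma_p`, `sigma_u`, `sigma_v`, `p[i]`,
#'   `u[j]`, `v[i]`), chain ids, index maps, data, priors and a convergence
#'   flag. If any split-R-hat is >= 1.02 the fit is flagged (with a warning),
#'   never silently returned as converged.
#' @examples
#' \donttest{
#' set.seed(7)
#' d <- design_spec(10, 16)
#' trials <- simulate_trials(d, draw_parameters(d, "M1", 0.2))
#' fit <- fit_truth_model(trials, "M1",
#'   settings = mcmc_settings_desk(chains = 2, warmup = 150, draws = 300))
#' tidy(fit)
#' }
#' @export
fit_truth_model <- function(trials, variant,
                            priors = prior_spec(variant),
                            settings = mcmc_settings_desk(),
                            link = link_spec(),
                            engine = c("gibbs", "jags"), quiet = TRUE) {
  variant <- as_variant(variant)
  engine <- match.arg(engine)
  stopifnot(inherits(priors, "prior_spec"), inherits(settings, "mcmc_settings"),
            inherits(link, "link_spec"))
  if (priors$variant != variant) {
    stop("`priors` were built for variant ", priors$variant, ", not ", variant,
         ".", call. = FALSE)
  }
  validate_trials(trials, allow_empty = TRUE)
  if (nrow(trials) == 0) {
    return(prior_only_fit(variant, priors, settings, link))
  }

  statement_levels <- sort(unique(trials$statement_id))
  participant_levels <- sort(unique(trials$participant_id))
  item <- match(trials$statement_id, statement_levels)
  subj <- match(trials$participant_id, participant_levels)
  S <- length(statement_levels)
  P <- length(participant_levels)

  if (engine == "gibbs") {
    chain_draws <- lapply(seq_len(settings$chains), function(k) {
      run_gibbs_chain(
        y = as.integer(trials$judgment), item = item, subj = subj,
        Rv = as.integer(trials$repeated), S = S, P = P,
        variant = variant, priors = priors, link = link,
        warmup = settings$warmup, draws = settings$draws,
        seed = settings$seed + k
      )
    })
    mcmc <- coda::mcmc.list(lapply(chain_draws, coda::mcmc))
    draws <- do.call(rbind, chain_draws)
  } else {
    inits <- lapply(seq_len(settings$chains), function(k) {
      list(m = priors$m_mean, mu_p = priors$mu_p_mean,
           sigma_p = 0.5, sigma_u = 0.3, sigma_v = 0.15,
           p = rep(priors$mu_p_mean, S), u = rep(0, P), v = rep(0, S),
           .RNG.name = "base::Mersenne-Twister",
           .RNG.seed = settings$seed + k)
    })
    jm <- rjags::jags.model(
      textConnection(jags_model_string(variant, priors, link)),
      data = list(y = as.integer(trials$judgment), item = item, subj = subj,
                  R = as.integer(trials$repeated), N = nrow(trials),
                  S = S, P = P),
      inits = inits, n.chains = settings$chains,
      n.adapt = max(100L, settings$warmup %/% 2L), quiet = quiet
    )
    update(jm, settings$warmup)
    mcmc <- rjags::coda.samples(
      jm, variable.names = c("m", "mu_p", "sigma_p", "sigma_u", "sigma_v",
                             "p", "u", "v"),
      n.iter = settings$draws
    )
    draws <- do.call(rbind, lapply(mcmc, as.matrix))
  }
  chain_id <- rep(seq_len(settings$chains), each = settings$draws)

  fit <- structure(list(
    variant = variant, priors = priors, settings = settings, link = link,
    draws = draws, chain_id = chain_id, mcmc = mcmc, engine = engine,
    trials = tibble::as_tibble(trials),
    statement_levels = statement_levels, participant_levels = participant_levels,
    item = item, subj = subj,
    prior_only = FALSE,
    data_fingerprint = sprintf("%d trials; %d statements; %d participants; sum(y)=%d",
                               nrow(trials), S, P, sum(trials$judgment))
  ), class = "truth_fit")

  diag <- diagnostics(fit)
  fit$converged <- all(diag$rhat < 1.02, na.rm = TRUE)
  if (!fit$converged) {
    warning("Fit flagged as non-converged: max split R-hat = ",
            signif(max(diag$rhat, na.rm = TRUE), 4), call. = FALSE)
  }
  fit
}

#' @export
print.truth_fit <- function(x, ...) {
  cat("<truth_fit>", x$variant,
      if (x$prior_only) "(prior only)" else x$data_fingerprint, "\n")
  cat("  draws:", nrow(x$draws), "(", x$settings$chains, "chains )",
      if (!isTRUE(x$converged)) " ** NOT CONVERGED **" else "", "\n")
  if (!x$prior_only) {
    cat(sprintf("  m: posterior mean %.3f (sd %.3f)\n",
                mean(x$draws[, "m"]), sd(x$draws[, "m"])))
  }
  invisible(x)
}

#' Pointwise log-likelihood matrix of a fitted model
#'
#' Evaluates, for every posterior draw and every trial, the Bernoulli-probit
#' log-likelihood implied by the drawn parameters. Used by PSIS-LOO and by
#' the bridge sampler.
#'
#' @param fit A `truth_fit`.
#' @param draws Optional draw matrix with the fit's column layout (defaults
#'   to the fit's own posterior draws).
#' @return A numeric matrix, draws x trials. Zero-column matrix for a
#'   prior-only fit.
#' @export
pointwise_loglik <- function(fit, draws = NULL) {
  stopifnot(inherits(fit, "truth_fit"))
  if (is.null(draws)) draws <- fit$draws
  n <- nrow(fit$trials)
  if (n == 0) return(matrix(0, nrow(draws), 0))
  S <- length(fit$statement_levels)
  P <- length(fit$participant_levels)
  p_mat <- draws[, paste0("p[", seq_len(S), "]"), drop = FALSE]
  u_mat <- draws[, paste0("u[", seq_len(P), "]"), drop = FALSE]
  v_mat <- draws[, paste0("v[", seq_len(S), "]"), drop = FALSE]
  m <- draws[, "m"]
  f_mat <- switch(fit$variant,
    M1 = matrix(m, nrow(draws), S),
    M2 = m * p_mat,
    M3 = m * (1 - p_mat),
    M4 = 2 * m * (0.5 - abs(p_mat - 0.5))
  )
  rep_flag <- fit$trials$repeated
  eta <- p_mat[, fit$item, drop = FALSE] +
    matrix(rep_flag, nrow(draws), n, byrow = TRUE) *
      (f_mat[, fit$item, drop = FALSE] + v_mat[, fit$item, drop = FALSE]) +
    u_mat[, fit$subj, drop = FALSE]
  theta <- pnorm((eta - fit$link$threshold) / fit$link$sigma)
  theta <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
  y <- matrix(fit$trials$judgment, nrow(draws), n, byrow = TRUE)
  y * log(theta) + (1 - y) * log1p(-theta)
}

split_rhat_one <- function(x, chain_id) {
  halves <- unlist(lapply(split(x, chain_id), function(ch) {
    h <- length(ch) %/% 2L
    list(ch[seq_len(h)], ch[h + seq_len(h)])
  }), recursive = FALSE)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  n <- length(halves[[1]])
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics of an MCMC run
#'
#' Split R-hat (each chain split in half) and effective sample size for every
#' monitored parameter, with pass/fail flags against the thresholds
#' `rhat < 1.02` and a configurable ESS floor.
#'
#' @param fit A `truth_fit`, or a numeric draw matrix (then `chain_id` is
#'   required).
#' @param chain_id Integer chain labels per row (matrix input only).
#' @param min_ess Minimum acceptable ESS (default 100).
#' @return A tibble: `parameter`, `rhat`, `ess`, `rhat_ok`, `ess_ok`.
#' @export
diagnostics <- function(fit, chain_id = NULL, min_ess = 100) {
  if (inherits(fit, "truth_fit")) {
    if (fit$prior_only) {
      draws <- fit$draws
      chain_id <- fit$chain_id
      ess <- coda::effectiveSize(coda::mcmc(draws))
    } else {
      draws <- fit$draws
      chain_id <- fit$chain_id
      ess <- coda::effectiveSize(fit$mcmc)
    }
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain_id)) stop("`chain_id` required for matrix input.", call. = FALSE)
    ess <- coda::effectiveSize(coda::mcmc(draws))
  }
  rhat <- apply(draws, 2, split_rhat_one, chain_id = chain_id)
  tibble::tibble(
    parameter = colnames(draws),
    rhat = unname(rhat),
    ess = unname(ess[colnames(draws)]),
    rhat_ok = .data$rhat < 1.02,
    ess_ok = .data$ess >= min_ess
  )
}

#' Highest density interval of a sample
#'
#' @param x Numeric draws.
#' @param prob Mass covered (default 0.95).
#' @return Length-2 vector (lower, upper). Degenerate draws give a
#'   zero-width interval.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Posterior summaries of a fitted model
#'
#' Mean, sd and 95% HDI for the hyper-parameters, plus the posterior of the
#' *realized* variances of the random-effect vectors (`var(u)`, `var(v)`),
#' which is how participant-level variation is usually reported in this
#' literature (alongside `sigma_u^2` itself).
#'
#' @param fit A `truth_fit`.
#' @param prob HDI mass.
#' @param include_random Also list every `p[i]`, `u[j]`, `v[i]`.
#' @return A tibble: `parameter`, `mean`, `sd`, `hdi_lo`, `hdi_hi`.
#' @export
posterior_summary <- function(fit, prob = 0.95, include_random = FALSE) {
  stopifnot(inherits(fit, "truth_fit"))
  draws <- fit$draws
  pars <- intersect(c("m", "mu_p", "sigma_p", "sigma_u", "sigma_v"), colnames(draws))
  mat <- draws[, pars, drop = FALSE]
  if (!fit$prior_only) {
    P <- length(fit$participant_levels)
    S <- length(fit$statement_levels)
    u_mat <- draws[, paste0("u[", seq_len(P), "]"), drop = FALSE]
    v_mat <- draws[, paste0("v[", seq_len(S), "]"), drop = FALSE]
    extra <- cbind(
      `var(u)` = apply(u_mat, 1, var),
      `var(v)` = apply(v_mat, 1, var),
      `sigma_u^2` = draws[, "sigma_u"]^2,
      `sigma_v^2` = draws[, "sigma_v"]^2
    )
    mat <- cbind(mat, extra)
    if (include_random) {
      mat <- cbind(mat, draws[, setdiff(colnames(draws), pars), drop = FALSE])
    }
  }
  purrr::map_dfr(colnames(mat), function(nm) {
    x <- mat[, nm]
    h <- hdi(x, prob)
    tibble::tibble(parameter = nm, mean = mean(x), sd = sd(x),
                   hdi_lo = h[1], hdi_hi = h[2])
  })
}

#' @method tidy truth_fit
#' @export
tidy.truth_fit <- function(x, ...) posterior_summary(x, ...)

#' @method glance truth_fit
#' @export
glance.truth_fit <- function(x, ...) {
  diag <- diagnostics(x)
  tibble::tibble(
    variant = x$variant,
    n_trials = nrow(x$trials),
    n_statements = length(x$statement_levels),
    n_participants = length(x$participant_levels),
    n_draws = nrow(x$draws),
    chains = x$settings$chains,
    max_rhat = max(diag$rhat, na.rm = TRUE),
    min_ess = min(diag$ess, na.rm = TRUE),
    converged = isTRUE(x$converged)
  )
}

#' Plot fitted truth-effect curves over item summaries
#'
#' Draws the posterior-mean analytic curve of the fitted variant (with an
#' HDI band over posterior draws of `m`) on top of the observed per-item
#' truth effects.
#'
#' @param object A `truth_fit`.
#' @param x_mode x-axis operationalization.
#' @param n_draws Number of posterior draws used for the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot truth_fit
#' @export
autoplot.truth_fit <- function(object, x_mode = c("mean_RN", "new_only"),
                               n_draws = 200, ...) {
  x_mode <- match.arg(x_mode)
  items <- summarize_items(object$trials)
  idx <- round(seq(1, nrow(object$draws), length.out = min(n_draws, nrow(object$draws))))
  m_draws <- object$draws[idx, "m"]
  grid <- seq(-1, 2, by = 0.02)
  band <- purrr::map_dfr(m_draws, function(m)
    truth_effect_curve(object$variant, m, grid, object$link)) |>
    dplyr::group_by(.data$p) |>
    dplyr::summarise(
      lo = quantile(.data$truth_effect, 0.025),
      hi = quantile(.data$truth_effect, 0.975),
      theta_new = .data$theta_new[1],
      perceived_truth_mean = mean(.data$perceived_truth_mean),
      .groups = "drop"
    )
  mean_curve <- truth_effect_curve(object$variant, mean(object$draws[, "m"]),
                                   grid, object$link)
  xcol_band <- if (x_mode == "mean_RN") "perceived_truth_mean" else "theta_new"
  xcol_curve <- if (x_mode == "mean_RN") "perceived_truth_mean" else "perceived_truth_N"
  plot_item_effects(items, x_mode) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data[[xcol_band]], ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, alpha = 0.25, fill = "steelblue"
    ) +
    ggplot2::geom_line(
      data = mean_curve,
      ggplot2::aes(x = .data[[xcol_curve]], y = .data$truth_effect),
      colour = "steelblue"
    ) +
    ggplot2::ggtitle(paste0(object$variant, ": posterior mean m = ",
                            signif(mean(object$draws[, "m"]), 3)))
}
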