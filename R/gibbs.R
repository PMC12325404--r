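## Blocked data-augmentation Gibbs sampler for the hierarchical probit model.
##
## The latent-threshold formulation makes the model conditionally linear and
## Gaussian: augmenting each trial with its latent truth value y* (a
## truncated normal given the observed judgment) yields exact normal
## conditionals for the plausibilities p, the random effects u and v, the
## hyper-mean mu_p and (truncated at zero) the fluency magnitude m, for every
## variant in which the linear predictor is linear in the block being
## updated. That covers p under M1-M3 (the coefficient of p_i is 1, 1 + R*m
## and 1 - R*m respectively) and m under all four variants. The remaining
## blocks - the three scale parameters and p under M4 (whose triangular
## shift is only piecewise linear in p) - use random-walk Metropolis steps
## with scales adapted during warmup.

sum_by <- function(x, g, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

# Half-normal-prior scale update: random walk on log(sigma).
mh_sigma <- function(sigma, values, hyper_sd, step) {
  n <- length(values)
  ss <- sum(values^2)
  lt <- function(s) -n * log(s) - ss / (2 * s^2) + dnorm(s, 0, hyper_sd, log = TRUE)
  prop <- sigma * exp(rnorm(1, 0, step))
  lr <- lt(prop) - lt(sigma) + log(prop) - log(sigma)
  if (is.finite(lr) && log(runif(1)) < lr) c(prop, 1) else c(sigma, 0)
}

rtruncnorm_scalar <- function(mean, sd, lower = 0) {
  lo <- pnorm(lower, mean, sd)
  q <- min(max(lo + runif(1) * (1 - lo), 1e-15), 1 - 1e-15)
  qnorm(q, mean, sd)
}

run_gibbs_chain <- function(y, item, subj, Rv, S, P, variant, priors, link,
                            warmup, draws, seed) {
  set.seed(seed)
  N <- length(y)
  sigma <- link$sigma; thr <- link$threshold; s2 <- sigma^2
  n_subj <- tabulate(subj, P)
  rep_rows <- which(Rv == 1L)
  item_rep <- item[rep_rows]
  n_item_rep <- tabulate(item_rep, S)
  is_one <- y == 1L

  # initial state, jittered per chain
  p <- rep(priors$mu_p_mean, S) + rnorm(S, 0, 0.1)
  u <- numeric(P); v <- numeric(S)
  m <- abs(priors$m_mean + rnorm(1, 0, priors$m_sd / 4)) + 1e-4
  mu_p <- priors$mu_p_mean
  sp <- 0.5; su <- 0.3; sv <- 0.15
  steps <- c(sp = 0.3, su = 0.3, sv = 0.4, p4 = 0.2, pmh = 0.3)
  acc <- c(sp = 0, su = 0, sv = 0, p4 = 0, pmh = 0)
  window <- 0L

  total <- warmup + draws
  out <- matrix(NA_real_, draws, 5 + 2 * S + P)
  colnames(out) <- c("m", "mu_p", "sigma_p", "sigma_u", "sigma_v",
                     paste0("p[", seq_len(S), "]"),
                     paste0("u[", seq_len(P), "]"),
                     paste0("v[", seq_len(S), "]"))

  fl <- function(m, p) fluency_shift(variant, m, p)

  bern_ll <- function(pv) {
    fv <- fl(m, pv)
    e <- pv[item] + Rv * (fv[item] + v[item]) + u[subj]
    th <- pnorm((e - thr) / sigma)
    th <- pmin(pmax(th, 1e-12), 1 - 1e-12)
    ifelse(is_one, log(th), log1p(-th))
  }

  for (iter in seq_len(total)) {
    # -- marginal Metropolis refresh of p against the Bernoulli likelihood
    # (y* integrated out; run before the augmentation step, making this a
    # partially collapsed update). The conjugate update below mixes well for
    # informative items but crawls for near-deterministic extreme items,
    # whose latent values live in the far tail; this step fixes that.
    prop <- p + rnorm(S, 0, steps[["pmh"]])
    dl <- sum_by(bern_ll(prop) - bern_ll(p), item, S) +
      dnorm(prop, mu_p, sp, log = TRUE) - dnorm(p, mu_p, sp, log = TRUE)
    take <- log(runif(S)) < dl
    p[take] <- prop[take]
    acc[["pmh"]] <- acc[["pmh"]] + mean(take)

    # -- latent truth values, truncated by the observed judgment
    f <- fl(m, p)
    eta <- p[item] + Rv * (f[item] + v[item]) + u[subj]
    plo <- pnorm((thr - eta) / sigma)
    uu <- runif(N)
    q <- ifelse(is_one, plo + uu * (1 - plo), uu * plo)
    ystar <- eta + sigma * qnorm(pmin(pmax(q, 1e-15), 1 - 1e-15))

    # -- participant biases u_j (normal conditional)
    r_u <- ystar - p[item] - Rv * (f[item] + v[item])
    prec_u <- n_subj / s2 + 1 / su^2
    u <- rnorm(P, (sum_by(r_u, subj, P) / s2) / prec_u, sqrt(1 / prec_u))

    # -- item residual shifts v_i (repeated trials only)
    r_v <- (ystar - p[item] - Rv * f[item] - u[subj])[rep_rows]
    prec_v <- n_item_rep / s2 + 1 / sv^2
    v <- rnorm(S, (sum_by(r_v, item_rep, S) / s2) / prec_v, sqrt(1 / prec_v))

    # -- plausibilities p_i
    if (variant == "M4") {
      prop <- p + rnorm(S, 0, steps[["p4"]])
      sqres <- function(pv) {
        fv <- fl(m, pv)
        e <- pv[item] + Rv * (fv[item] + v[item]) + u[subj]
        -(ystar - e)^2 / (2 * s2)
      }
      dl <- sum_by(sqres(prop) - sqres(p), item, S) +
        dnorm(prop, mu_p, sp, log = TRUE) - dnorm(p, mu_p, sp, log = TRUE)
      take <- log(runif(S)) < dl
      p[take] <- prop[take]
      acc[["p4"]] <- acc[["p4"]] + mean(take)
    } else {
      cvec <- switch(variant, M1 = rep(1, N), M2 = 1 + Rv * m, M3 = 1 - Rv * m)
      tvec <- switch(variant,
        M1 = ystar - Rv * (m + v[item]) - u[subj],
        M2 = ystar - Rv * v[item] - u[subj],
        M3 = ystar - Rv * (m + v[item]) - u[subj]
      )
      prec_p <- sum_by(cvec^2, item, S) / s2 + 1 / sp^2
      mean_p <- (sum_by(cvec * tvec, item, S) / s2 + mu_p / sp^2) / prec_p
      p <- rnorm(S, mean_p, sqrt(1 / prec_p))
    }

    # -- fluency magnitude m (truncated-normal conditional)
    g <- switch(variant, M1 = rep(1, S), M2 = p, M3 = 1 - p,
                M4 = 2 * (0.5 - abs(p - 0.5)))
    dvec <- Rv * g[item]
    t_m <- ystar - p[item] - Rv * v[item] - u[subj]
    prec_m <- sum(dvec^2) / s2 + 1 / priors$m_sd^2
    mean_m <- (sum(dvec * t_m) / s2 + priors$m_mean / priors$m_sd^2) / prec_m
    m <- rtruncnorm_scalar(mean_m, sqrt(1 / prec_m))

    # -- hyper-mean of plausibility
    prec_mu <- S / sp^2 + 1 / priors$mu_p_sd^2
    mu_p <- rnorm(1, (sum(p) / sp^2 + priors$mu_p_mean / priors$mu_p_sd^2) / prec_mu,
                  sqrt(1 / prec_mu))

    # -- scales (random-walk Metropolis on the log scale)
    r <- mh_sigma(sp, p - mu_p, priors$sigma_p_sd, steps[["sp"]])
    sp <- r[1]; acc[["sp"]] <- acc[["sp"]] + r[2]
    r <- mh_sigma(su, u, priors$sigma_u_sd, steps[["su"]])
    su <- r[1]; acc[["su"]] <- acc[["su"]] + r[2]
    r <- mh_sigma(sv, v, priors$sigma_v_sd, steps[["sv"]])
    sv <- r[1]; acc[["sv"]] <- acc[["sv"]] + r[2]

    # -- interweaving (ASIS): redraw the random-effect scales in the
    # non-centered parameterization, where the linear predictor is linear in
    # the scale, giving an exact truncated-normal conditional. This breaks
    # the strong coupling between a scale and its effect vector that makes
    # the centered-only update mix slowly.
    f <- fl(m, p)
    if (su > 1e-8) {
      ut <- u / su
      a <- ut[subj]
      t_s <- ystar - p[item] - Rv * (f[item] + v[item])
      prec <- sum(a^2) / s2 + 1 / priors$sigma_u_sd^2
      su <- rtruncnorm_scalar(sum(a * t_s) / s2 / prec, sqrt(1 / prec))
      u <- su * ut
    }
    if (sv > 1e-8) {
      vt <- v / sv
      a <- vt[item_rep]
      t_s <- (ystar - p[item] - Rv * f[item] - u[subj])[rep_rows]
      prec <- sum(a^2) / s2 + 1 / priors$sigma_v_sd^2
      sv <- rtruncnorm_scalar(sum(a * t_s) / s2 / prec, sqrt(1 / prec))
      v <- sv * vt
    }

    # adapt proposal scales toward ~40% acceptance during warmup
    window <- window + 1L
    if (iter <= warmup && window == 50L) {
      steps <- steps * exp(pmin(pmax(acc / 50 - 0.4, -0.3), 0.3))
      acc[] <- 0
      window <- 0L
    }

    if (iter > warmup) {
      out[iter - warmup, ] <- c(m, mu_p, sp, su, sv, p, u, v)
    }
  }
  out
}
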