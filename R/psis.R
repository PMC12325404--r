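## Pareto-smoothed importance sampling (PSIS) and PSIS-LOO.

gpd_fit <- function(x) {
  # Zhang & Stephens (2009) posterior-mean estimator of the generalized
  # Pareto shape/scale from exceedances x > 0
  x <- sort(x)
  n <- length(x)
  prior <- 3
  M <- 30L + floor(sqrt(n))
  theta <- 1 / x[n] +
    (1 - sqrt(M / (seq_len(M) - 0.5))) / (prior * x[max(1L, floor(n / 4 + 0.5))])
  lx <- vapply(theta, function(t) {
    k <- -mean(log1p(-t * x))
    n * (log(t / k) + k - 1)
  }, 0)
  w <- exp(lx - max(lx))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  list(k = k, sigma = k / theta_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

psis_smooth <- function(lw) {
  # Smooth the right tail of one vector of (unnormalized) log weights.
  s <- length(lw)
  lw <- lw - max(lw)
  tail_len <- as.integer(ceiling(min(0.2 * s, 3 * sqrt(s))))
  if (tail_len < 5) {
    return(list(lw = lw, k = NA_real_))
  }
  ord <- order(lw)
  tail_idx <- ord[(s - tail_len + 1):s]
  cut <- lw[ord[s - tail_len]]
  exc <- exp(lw[tail_idx]) - exp(cut)
  if (all(exc <= 0) || length(unique(exc)) < 2) {
    return(list(lw = lw, k = NA_real_))
  }
  fitk <- gpd_fit(exc[exc > 0])
  pp <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(exp(cut) + qgpd(pp, fitk$k, fitk$sigma))
  lw[tail_idx[order(lw[tail_idx])]] <- pmin(smoothed, 0)
  list(lw = lw, k = fitk$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Approximate leave-one-out cross-validation from the pointwise
#' log-likelihood matrix: per observation, importance weights proportional
#' to the inverse likelihood are stabilized by Pareto-smoothing their right
#' tail, then combined into the LOO predictive density. Reported on the sum
#' scale (ELPD = sum over observations), with a standard error and the
#' per-observation Pareto-k diagnostics. Many k values above 0.7 indicate an
#' unreliable approximation and trigger a warning.
#'
#' @param fit A `truth_fit`, or a draws x observations log-likelihood matrix.
#' @return List: `elpd`, `se`, `pointwise` (per-observation elpd), `pareto_k`,
#'   `n_bad_k`.
#' @export
loo_elpd <- function(fit) {
  ll <- if (inherits(fit, "truth_fit")) pointwise_loglik(fit) else as.matrix(fit)
  n <- ncol(ll)
  if (n == 0) {
    return(list(elpd = 0, se = 0, pointwise = numeric(), pareto_k = numeric(),
                n_bad_k = 0L))
  }
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$lw - log_sum_exp(sm$lw)
    pointwise[i] <- log_sum_exp(lw + ll[, i])
    pareto_k[i] <- sm$k
  }
  n_bad <- sum(pareto_k > 0.7, na.rm = TRUE)
  if (n_bad > 0) {
    warning(n_bad, " observation(s) with Pareto k > 0.7; PSIS-LOO may be unreliable.",
            call. = FALSE)
  }
  list(elpd = sum(pointwise), se = sd(pointwise) * sqrt(n),
       pointwise = pointwise, pareto_k = pareto_k, n_bad_k = n_bad)
}

#' Pairwise ELPD difference with its standard error
#'
#' @param loo_a,loo_b Results of [loo_elpd()] on the *same* observations.
#' @return List: `elpd_diff` (a minus b), `se_diff`.
#' @export
elpd_diff <- function(loo_a, loo_b) {
  stopifnot(length(loo_a$pointwise) == length(loo_b$pointwise))
  d <- loo_a$pointwise - loo_b$pointwise
  list(elpd_diff = sum(d), se_diff = sd(d) * sqrt(length(d)))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
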