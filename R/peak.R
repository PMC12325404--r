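#' Quadratic regression of the per-item truth effect
#'
#' Ordinary least squares of the observed truth effect `R - N` on perceived
#' truth and its square, the regression behind the classic midpoint test: if
#' the fluency shift is constant on the probit scale, the fitted inverted-U
#' peaks at perceived truth .50.
#'
#' @param items Output of [summarize_items()] (items with an undefined
#'   proportion in either condition are dropped).
#' @param x_mode `"mean_RN"` (perceived truth as `(R+N)/2`) or `"new_only"`
#'   (`N` alone, the operationalization that avoids post-manipulation
#'   values).
#' @return Named numeric vector `c(b0, b1, b2)`.
#' @examples
#' x <- seq(0.1, 0.9, length.out = 10)
#' items <- tibble::tibble(statement_id = 1:10, prop_new = x, prop_rep = x,
#'   truth_effect = -(x - 0.5)^2 + 0.1, perceived_truth_mean = x,
#'   n_new = 10, n_rep = 10, complete = TRUE)
#' quadratic_fit(items)
#' @export
quadratic_fit <- function(items, x_mode = c("mean_RN", "new_only")) {
  x_mode <- match.arg(x_mode)
  xy <- peak_xy(items, x_mode)
  if (length(xy$x) < 3) {
    stop("Need at least 3 items with defined proportions.", call. = FALSE)
  }
  if (length(unique(xy$x)) < 3) {
    stop("Rank-deficient design: fewer than 3 distinct x values.", call. = FALSE)
  }
  fit <- lm(y ~ x + I(x^2), data = data.frame(x = xy$x, y = xy$y))
  setNames(unname(coef(fit)), c("b0", "b1", "b2"))
}

peak_xy <- function(items, x_mode) {
  xcol <- if (x_mode == "mean_RN") "perceived_truth_mean" else "prop_new"
  keep <- is.finite(items[[xcol]]) & is.finite(items$truth_effect)
  list(x = items[[xcol]][keep], y = items$truth_effect[keep])
}

#' Peak location of a fitted quadratic
#'
#' @param coefficients Vector with named elements `b1` and `b2` (e.g., from
#'   [quadratic_fit()]).
#' @return `-b1 / (2 * b2)` when `b2 < 0`; `NA_real_` when `b2 >= 0`, the
#'   designated "no interior peak" outcome (an upward-opening or flat
#'   quadratic has no interior maximum).
#' @examples
#' peak_location(c(b0 = 0, b1 = 1, b2 = -1))
#' @export
peak_location <- function(coefficients) {
  b1 <- coefficients[["b1"]]
  b2 <- coefficients[["b2"]]
  if (!is.finite(b1) || !is.finite(b2) || b2 >= 0) return(NA_real_)
  -b1 / (2 * b2)
}

## Vectorized bootstrap peaks: closed-form 3x3 normal equations per resample.
boot_peaks <- function(x, y, n_bootstrap) {
  n <- length(x)
  B <- matrix(sample.int(n, n * n_bootstrap, replace = TRUE), n_bootstrap, n)
  x2 <- x^2
  rs <- function(q) rowSums(matrix(q[B], n_bootstrap, n))
  Sx <- rs(x); Sx2 <- rs(x2); Sx3 <- rs(x * x2); Sx4 <- rs(x2 * x2)
  Sy <- rs(y); Sxy <- rs(x * y); Sx2y <- rs(x2 * y)
  det_a <- n * (Sx2 * Sx4 - Sx3^2) - Sx * (Sx * Sx4 - Sx3 * Sx2) +
    Sx2 * (Sx * Sx3 - Sx2^2)
  det_b1 <- n * (Sxy * Sx4 - Sx3 * Sx2y) - Sy * (Sx * Sx4 - Sx3 * Sx2) +
    Sx2 * (Sx * Sx2y - Sxy * Sx2)
  det_b2 <- n * (Sx2 * Sx2y - Sxy * Sx3) - Sx * (Sx * Sx2y - Sxy * Sx2) +
    Sy * (Sx * Sx3 - Sx2^2)
  b1 <- det_b1 / det_a
  b2 <- det_b2 / det_a
  ok <- is.finite(b1) & is.finite(b2) & b2 < 0
  list(peaks = -b1[ok] / (2 * b2[ok]), n_degenerate = sum(!ok))
}

#' Bootstrap confidence interval for the peak of the truth-effect curve
#'
#' Resamples statements with replacement, refits the quadratic regression on
#' each resample, and forms a percentile confidence interval for the peak
#' location `-b1/(2*b2)`. Resamples without an interior peak (`b2 >= 0`) are
#' excluded from the percentile computation and counted; if more than half
#' of the resamples are degenerate the result is flagged unreliable. The
#' null hypothesis of a peak at `midpoint` (.50, the constant-shift
#' signature) is rejected iff the midpoint falls outside the interval.
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param items Output of [summarize_items()].
#' @param x_mode x-axis operationalization, see [quadratic_fit()].
#' @param n_bootstrap Number of resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param midpoint Null peak location (default 0.50).
#' @return A `peak_test_result`: list with `coefficients`, `peak`, `ci_lo`,
#'   `ci_hi`, `level`, `midpoint`, `reject`, `n_bootstrap`, `n_degenerate`,
#'   `reliable`.
#' @examples
#' set.seed(1)
#' d <- design_spec(20, 60)
#' items <- summarize_items(simulate_trials(d, draw_parameters(d, "M2", 0.4)))
#' bootstrap_peak_ci(items, n_bootstrap = 500)
#' @export
bootstrap_peak_ci <- function(items, x_mode = c("mean_RN", "new_only"),
                              n_bootstrap = 5000, level = 0.95,
                              midpoint = 0.50) {
  x_mode <- match.arg(x_mode)
  coefs <- quadratic_fit(items, x_mode)
  xy <- peak_xy(items, x_mode)
  bp <- boot_peaks(xy$x, xy$y, n_bootstrap)
  alpha <- (1 - level) / 2
  if (length(bp$peaks) == 0) {
    ci <- c(NA_real_, NA_real_)
  } else {
    ci <- unname(quantile(bp$peaks, c(alpha, 1 - alpha)))
  }
  reliable <- bp$n_degenerate <= n_bootstrap / 2
  if (!reliable) {
    warning("More than half of the bootstrap resamples had no interior peak; ",
            "the interval is unreliable.", call. = FALSE)
  }
  structure(list(
    coefficients = coefs,
    peak = peak_location(coefs),
    ci_lo = ci[1], ci_hi = ci[2],
    level = level, midpoint = midpoint,
    reject = isTRUE(ci[1] > midpoint | ci[2] < midpoint),
    n_bootstrap = n_bootstrap,
    n_degenerate = bp$n_degenerate,
    reliable = reliable,
    x_mode = x_mode
  ), class = "peak_test_result")
}

#' @export
print.peak_test_result <- function(x, ...) {
  cat(sprintf("<peak_test_result> peak = %.4f, %d%% CI [%.4f, %.4f]; %s midpoint %.2f\n",
              x$peak, round(100 * x$level), x$ci_lo, x$ci_hi,
              if (x$reject) "REJECTS" else "does not reject", x$midpoint))
  if (x$n_degenerate > 0) {
    cat("  (", x$n_degenerate, "of", x$n_bootstrap,
        "resamples had no interior peak )\n")
  }
  invisible(x)
}

#' @method tidy peak_test_result
#' @export
tidy.peak_test_result <- function(x, ...) {
  tibble::tibble(
    b0 = x$coefficients[["b0"]], b1 = x$coefficients[["b1"]],
    b2 = x$coefficients[["b2"]],
    peak = x$peak, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    level = x$level, midpoint = x$midpoint, reject = x$reject,
    n_bootstrap = x$n_bootstrap, n_degenerate = x$n_degenerate,
    reliable = x$reliable
  )
}

## One synthetic item-level dataset under the documented power recipe:
## 80 statements on the uniform [-1, 2] grid, `n_judgments` binomial
## judgments per statement per condition, no item/participant residuals.
simulate_power_items <- function(variant, m, n_statements = 80,
                                 n_judgments = 250, link = link_spec()) {
  p <- seq(-1, 2, length.out = n_statements)
  theta_new <- prob_true_new(p, link)
  theta_rep <- prob_true_rep(variant, p, m, link)
  prop_new <- rbinom(n_statements, n_judgments, theta_new) / n_judgments
  prop_rep <- rbinom(n_statements, n_judgments, theta_rep) / n_judgments
  tibble::tibble(
    statement_id = seq_len(n_statements),
    prop_new = prop_new, prop_rep = prop_rep,
    truth_effect = prop_rep - prop_new,
    perceived_truth_mean = (prop_rep + prop_new) / 2,
    n_new = n_judgments, n_rep = n_judgments,
    complete = TRUE
  )
}

#' Monte Carlo power study of the bootstrap midpoint test
#'
#' Simulates many item-level datasets under a given generating variant and
#' shift magnitude, applies the bootstrap midpoint test to each, and reports
#' the proportion of datasets whose confidence interval excludes the
#' midpoint. Under the constant-shift variant M1 this proportion estimates
#' the (slightly anti-conservative) type I error rate of the test; under the
#' other variants it estimates power.
#'
#' Each simulated dataset contains `n_statements` statements with
#' plausibility equally spaced on `[-1, 2]` and `n_judgments` binomial
#' judgments per statement per condition, with no item or participant
#' residual variation.
#'
#' @param variant Generating model variant.
#' @param m Shift magnitude.
#' @param n_datasets Number of simulated datasets (default 1000).
#' @param n_bootstrap Bootstrap resamples per dataset (default 5000).
#' @param n_statements Statements per dataset (default 80).
#' @param n_judgments Judgments per statement per condition (default 250).
#' @param x_mode x-axis operationalization (default `"mean_RN"`, as in the
#'   original test).
#' @param level,midpoint Test level and null peak location.
#' @param link A [link_spec()].
#' @return A `power_result`: list with `variant`, `m`, `n_datasets`,
#'   `rejection_rate`, `n_rejected`, recipe fields, and the per-dataset
#'   reject flags.
#' @examples
#' set.seed(1)
#' power_study("M2", 0.4, n_datasets = 20, n_bootstrap = 300)$rejection_rate
#' @export
power_study <- function(variant, m, n_datasets = 1000, n_bootstrap = 5000,
                        n_statements = 80, n_judgments = 250,
                        x_mode = c("mean_RN", "new_only"),
                        level = 0.95, midpoint = 0.50, link = link_spec()) {
  variant <- as_variant(variant)
  x_mode <- match.arg(x_mode)
  alpha <- (1 - level) / 2
  rejects <- logical(n_datasets)
  for (k in seq_len(n_datasets)) {
    items <- simulate_power_items(variant, m, n_statements, n_judgments, link)
    xy <- peak_xy(items, x_mode)
    bp <- boot_peaks(xy$x, xy$y, n_bootstrap)
    if (length(bp$peaks) == 0) {
      rejects[k] <- FALSE
      next
    }
    ci <- quantile(bp$peaks, c(alpha, 1 - alpha), names = FALSE)
    rejects[k] <- ci[1] > midpoint || ci[2] < midpoint
  }
  structure(list(
    variant = variant, m = m, n_datasets = n_datasets,
    rejection_rate = mean(rejects), n_rejected = sum(rejects),
    n_bootstrap = n_bootstrap, n_statements = n_statements,
    n_judgments = n_judgments, x_mode = x_mode,
    level = level, midpoint = midpoint,
    rejects = rejects
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> %s, m = %g: rejection rate %.1f%% (%d / %d datasets)\n",
              x$variant, x$m, 100 * x$rejection_rate, x$n_rejected, x$n_datasets))
  invisible(x)
}

#' @method tidy power_result
#' @export
tidy.power_result <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, m = x$m,
    rejection_rate = x$rejection_rate,
    n_datasets = x$n_datasets, n_bootstrap = x$n_bootstrap,
    n_statements = x$n_statements, n_judgments = x$n_judgments
  )
}
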