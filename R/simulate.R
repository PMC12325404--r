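#' Design of a simulated truth-judgment experiment
#'
#' Describes the sampling design used by the trial-level simulator: number of
#' statements and participants, where statement plausibility comes from, and
#' the random-effect standard deviations. In the standard repetition
#' paradigm every participant judges all statements after half of them were
#' shown in an exposure phase; which half is repeated is counterbalanced
#' across participants.
#'
#' @param n_statements Number of statements (must be even under the
#'   half-within-participant repetition scheme). Default 80.
#' @param n_participants Number of participants. Default 250.
#' @param plausibility_source `"grid_uniform"` (equally spaced on
#'   `[-1, 2]`) or `"normal_hierarchical"` (`Normal(mu_p, sigma_p)`).
#' @param mu_p,sigma_p Mean and sd of the plausibility distribution when
#'   `plausibility_source = "normal_hierarchical"`.
#' @param sigma_u Sd of participant-level response-bias effects `u_j`.
#' @param sigma_v Sd of item-level residual truth-effect shifts `v_i`.
#' @param repetition_scheme Currently only `"half_within_participant"`.
#' @param link A [link_spec()].
#' @return A `design_spec` object (list).
#' @examples
#' design_spec(n_statements = 20, n_participants = 40)
#' @export
design_spec <- function(n_statements = 80, n_participants = 250,
                        plausibility_source = c("grid_uniform", "normal_hierarchical"),
                        mu_p = 0.5, sigma_p = 0.75,
                        sigma_u = 0.3, sigma_v = 0.1,
                        repetition_scheme = "half_within_participant",
                        link = link_spec()) {
  plausibility_source <- match.arg(plausibility_source)
  repetition_scheme <- match.arg(repetition_scheme, "half_within_participant")
  stopifnot(
    n_statements >= 2, n_participants >= 1,
    sigma_p >= 0, sigma_u >= 0, sigma_v >= 0,
    inherits(link, "link_spec")
  )
  if (n_statements %% 2 != 0) {
    stop("`n_statements` must be even for the half-within-participant scheme.",
         call. = FALSE)
  }
  structure(list(
    n_statements = as.integer(n_statements),
    n_participants = as.integer(n_participants),
    plausibility_source = plausibility_source,
    mu_p = mu_p, sigma_p = sigma_p,
    sigma_u = sigma_u, sigma_v = sigma_v,
    repetition_scheme = repetition_scheme,
    link = link
  ), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>", x$n_statements, "statements x", x$n_participants,
      "participants;", x$plausibility_source,
      sprintf("; sigma_u = %g, sigma_v = %g\n", x$sigma_u, x$sigma_v))
  invisible(x)
}

#' Draw true generating parameters for a simulated experiment
#'
#' Samples statement plausibilities `p` (equally spaced on `[-1, 2]` under
#' `grid_uniform`, or `Normal(mu_p, sigma_p)`), item residual shifts
#' `v ~ Normal(0, sigma_v)` and participant biases `u ~ Normal(0, sigma_u)`.
#'
#' @param design A [design_spec()].
#' @param variant Model variant for the fluency shift.
#' @param m Shift magnitude (nonnegative).
#' @return A `truth_params` object: list with `p`, `v`, `u`, `m`, `variant`,
#'   `link`.
#' @examples
#' set.seed(1)
#' draw_parameters(design_spec(20, 10), "M1", m = 0.15)
#' @export
draw_parameters <- function(design, variant, m) {
  stopifnot(inherits(design, "design_spec"), is.numeric(m), m >= 0)
  variant <- as_variant(variant)
  p <- switch(design$plausibility_source,
    grid_uniform = seq(-1, 2, length.out = design$n_statements),
    normal_hierarchical = rnorm(design$n_statements, design$mu_p, design$sigma_p)
  )
  structure(list(
    p = p,
    v = rnorm(design$n_statements, 0, design$sigma_v),
    u = rnorm(design$n_participants, 0, design$sigma_u),
    m = m, variant = variant, link = design$link
  ), class = "truth_params")
}

#' Simulate one binary truth judgment via the latent-threshold path
#'
#' Draws a latent truth value `y* ~ Normal(p + shift, sigma)` and returns 1
#' iff `y*` exceeds the threshold. This is the generative route that the
#' probit link summarizes in closed form; it is retained because comparing
#' its Monte Carlo frequencies with `pnorm((p + shift - threshold)/sigma)`
#' is a direct check of that equivalence.
#'
#' @param p Latent plausibility (vectorized).
#' @param shift Additive latent shift (fluency plus residuals; vectorized).
#' @param link A [link_spec()].
#' @param n Number of draws per element of `p` (vector result is flattened
#'   column-wise when `length(p) > 1`).
#' @return Integer 0/1 vector of length `length(p) * n`.
#' @examples
#' set.seed(1)
#' mean(simulate_latent_judgment(1, 0, n = 1e4))
#' pnorm((1 - 0.5) / 0.5)
#' @export
simulate_latent_judgment <- function(p, shift = 0, link = link_spec(), n = 1L) {
  stopifnot(inherits(link, "link_spec"))
  mu <- rep(p + shift, times = n)
  ystar <- rnorm(length(mu), mean = mu, sd = link$sigma)
  as.integer(ystar > link$threshold)
}

repetition_matrix <- function(n_statements, n_participants) {
  ## Counterbalanced half split: participants come in complementary pairs, so
  ## each statement is repeated for n_participants/2 (+/- 1 if odd) of them.
  R <- matrix(0L, n_participants, n_statements)
  half <- n_statements %/% 2L
  j <- 1L
  while (j <= n_participants) {
    rep_set <- sample.int(n_statements, half)
    R[j, rep_set] <- 1L
    if (j + 1L <= n_participants) R[j + 1L, -rep_set] <- 1L
    j <- j + 2L
  }
  R
}

#' Simulate a trial-level truth-judgment table
#'
#' Generates one binary judgment per (participant, statement) pair. Within
#' each participant a random half of the statements is flagged repeated,
#' counterbalanced across participants so that each statement is repeated
#' for about half of the participants. The success probability is
#' `pnorm((p_i + R_ij * (f_i + v_i) + u_j - threshold) / sigma)`.
#'
#' @param design A [design_spec()].
#' @param params A `truth_params` object from [draw_parameters()] (or
#'   constructed by hand with matching lengths).
#' @return A tibble with columns `participant_id`, `statement_id`,
#'   `repeated` (0/1) and `judgment` (0/1).
#' @examples
#' set.seed(42)
#' d <- design_spec(10, 8)
#' simulate_trials(d, draw_parameters(d, "M1", 0.2))
#' @export
simulate_trials <- function(design, params) {
  stopifnot(inherits(design, "design_spec"), inherits(params, "truth_params"))
  S <- design$n_statements
  P <- design$n_participants
  if (length(params$p) != S || length(params$v) != S || length(params$u) != P) {
    stop("`params` vector lengths do not match the design.", call. = FALSE)
  }
  link <- params$link
  R <- repetition_matrix(S, P)
  f <- fluency_shift(params$variant, params$m, params$p)
  item <- rep(seq_len(S), times = P)
  subj <- rep(seq_len(P), each = S)
  rep_flag <- as.integer(t(R))[seq_len(S * P)]
  eta <- params$p[item] + rep_flag * (f[item] + params$v[item]) + params$u[subj]
  theta <- pnorm((eta - link$threshold) / link$sigma)
  tibble::tibble(
    participant_id = subj,
    statement_id = item,
    repeated = rep_flag,
    judgment = rbinom(S * P, 1L, theta)
  )
}

#' Per-statement summaries of a trial table
#'
#' Computes, for each statement, the proportion of "true" responses in the
#' new condition (`prop_new`, often written N) and repeated condition
#' (`prop_rep`, R), the observed truth effect `R - N`, and the average
#' perceived truth `(R + N)/2`, together with the condition counts. A
#' statement with zero trials in a condition gets an `NA` proportion and is
#' flagged in `complete`.
#'
#' @param trials A trial table as produced by [simulate_trials()] or
#'   [read_trials()].
#' @return A tibble with one row per statement: `statement_id`, `prop_new`,
#'   `prop_rep`, `truth_effect`, `perceived_truth_mean`, `n_new`, `n_rep`,
#'   `complete`.
#' @examples
#' set.seed(1)
#' d <- design_spec(10, 20)
#' summarize_items(simulate_trials(d, draw_parameters(d, "M1", 0.2)))
#' @export
summarize_items <- function(trials) {
  validate_trials(trials)
  trials |>
    dplyr::group_by(.data$statement_id) |>
    dplyr::summarise(
      prop_new = if (sum(.data$repeated == 0) > 0)
        mean(.data$judgment[.data$repeated == 0]) else NA_real_,
      prop_rep = if (sum(.data$repeated == 1) > 0)
        mean(.data$judgment[.data$repeated == 1]) else NA_real_,
      n_new = sum(.data$repeated == 0),
      n_rep = sum(.data$repeated == 1),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      truth_effect = .data$prop_rep - .data$prop_new,
      perceived_truth_mean = (.data$prop_rep + .data$prop_new) / 2,
      complete = .data$n_new > 0 & .data$n_rep > 0
    ) |>
    dplyr::select("statement_id", "prop_new", "prop_rep", "truth_effect",
                  "perceived_truth_mean", "n_new", "n_rep", "complete")
}

#' Scatter plot of per-item truth effects
#'
#' @param items Output of [summarize_items()].
#' @param x_mode x-axis operationalization.
#' @param curve Optional tibble from [truth_effect_curve()] to overlay.
#' @return A ggplot object.
#' @export
plot_item_effects <- function(items, x_mode = c("mean_RN", "new_only"),
                              curve = NULL) {
  x_mode <- match.arg(x_mode)
  xcol <- if (x_mode == "mean_RN") "perceived_truth_mean" else "prop_new"
  gg <- ggplot2::ggplot(items, ggplot2::aes(x = .data[[xcol]], y = .data$truth_effect)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = if (x_mode == "mean_RN") "perceived truth (R + N)/2" else "perceived truth (N)",
      y = "truth effect (R - N)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    ccol <- if (x_mode == "mean_RN") "perceived_truth_mean" else "perceived_truth_N"
    gg <- gg + ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data[[ccol]], y = .data$truth_effect),
      colour = "firebrick"
    )
  }
  gg
}
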