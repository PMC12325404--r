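#' Latent probit link specification
#'
#' The latent-variable model behind binary truth judgments assumes a normal
#' distribution of latent truth values with standard deviation `sigma`,
#' dichotomized at `threshold`. The conventional choice in this literature is
#' a *non*-standardized link with `sigma = 0.5` and a cutoff at `0.5`, so the
#' probability of a "true" response to a new statement with latent
#' plausibility `p` is `pnorm((p - threshold) / sigma)`.
#'
#' @param sigma Standard deviation of the latent truth values. Must be > 0.
#' @param threshold Latent cutoff above which a judgment is "true".
#'
#' @return An object of class `link_spec`: a list with elements `sigma` and
#'   `threshold`.
#' @examples
#' link_spec()
#' prob_true_new(1, link_spec())
#' @export
link_spec <- function(sigma = 0.5, threshold = 0.5) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive finite number.", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop("`threshold` must be a single finite number.", call. = FALSE)
  }
  structure(list(sigma = sigma, threshold = threshold), class = "link_spec")
}

#' @export
print.link_spec <- function(x, ...) {
  cat("<link_spec> probit link: sigma =", x$sigma, ", threshold =", x$threshold, "\n")
  invisible(x)
}

#' The four admissible model-variant labels
#'
#' @return `c("M1", "M2", "M3", "M4")`.
#' @export
model_variants <- function() c("M1", "M2", "M3", "M4")

#' Validate a model-variant label
#'
#' The four variants differ only in how the fluency shift induced by
#' repetition depends on a statement's latent plausibility: constant (M1),
#' increasing with plausibility (M2), decreasing with plausibility (M3), or
#' triangular with a peak at plausibility 0.5 (M4).
#'
#' @param variant `"M1"`, `"M2"`, `"M3"` or `"M4"` (integers 1:4 accepted).
#' @return The matched variant label as a character scalar.
#' @examples
#' as_variant(2)
#' @export
as_variant <- function(variant) {
  if (is.numeric(variant) && length(variant) == 1L && variant %in% 1:4) {
    return(model_variants()[variant])
  }
  if (is.character(variant) && length(variant) == 1L && variant %in% model_variants()) {
    return(variant)
  }
  stop("`variant` must be one of ", paste(model_variants(), collapse = ", "),
       " (or 1:4).", call. = FALSE)
}

#' Probability of judging a new statement as true
#'
#' @param p Latent plausibility (vectorized; must be finite).
#' @param link A [link_spec()].
#' @return Probabilities `pnorm((p - threshold) / sigma)`.
#' @examples
#' prob_true_new(c(-1, 0.5, 2))
#' @export
prob_true_new <- function(p, link = link_spec()) {
  stopifnot(inherits(link, "link_spec"))
  if (!is.numeric(p) || any(!is.finite(p))) {
    stop("`p` must be finite numeric.", call. = FALSE)
  }
  pnorm((p - link$threshold) / link$sigma)
}

#' Fluency shift induced by repetition
#'
#' Computes the additive increment `f` to latent plausibility caused by
#' repeating a statement, under one of four variants:
#' \describe{
#'   \item{M1}{`f = m` (constant shift).}
#'   \item{M2}{`f = m * p` (larger shift for plausible statements).}
#'   \item{M3}{`f = m * (1 - p)` (larger shift for implausible statements).}
#'   \item{M4}{`f = 2 * m * (0.5 - abs(p - 0.5))`, a triangular function
#'     peaking at `p = 0.5`.}
#' }
#' The formulas are applied literally for `p` outside `[0, 1]`, where M2-M4
#' can produce negative shifts.
#'
#' @param variant Model variant, see [as_variant()].
#' @param m Nonnegative shift magnitude.
#' @param p Latent plausibility (vectorized).
#' @return Numeric vector of shifts.
#' @examples
#' fluency_shift("M4", m = 0.4, p = c(0, 0.5, 1))
#' @export
fluency_shift <- function(variant, m, p) {
  variant <- as_variant(variant)
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m >= 0)
  if (!is.numeric(p) || any(!is.finite(p))) {
    stop("`p` must be finite numeric.", call. = FALSE)
  }
  switch(variant,
    M1 = rep(m, length(p)),
    M2 = m * p,
    M3 = m * (1 - p),
    M4 = 2 * m * (0.5 - abs(p - 0.5))
  )
}

#' Probability of judging a repeated statement as true
#'
#' Adds the variant-specific fluency shift (and optionally an item-specific
#' residual shift) to the latent plausibility before applying the probit
#' link: `pnorm((p + f + item_residual - threshold) / sigma)`.
#'
#' @inheritParams fluency_shift
#' @param link A [link_spec()].
#' @param item_residual Item-level residual truth-effect shift (defaults 0).
#' @return Probabilities, equal to [prob_true_new()] when `m = 0` and
#'   `item_residual = 0`.
#' @examples
#' prob_true_rep("M1", p = 0.5, m = 0.4)
#' @export
prob_true_rep <- function(variant, p, m, link = link_spec(), item_residual = 0) {
  stopifnot(inherits(link, "link_spec"))
  f <- fluency_shift(variant, m, p)
  pnorm((p + f + item_residual - link$threshold) / link$sigma)
}

#' Analytic truth-effect curve over a plausibility grid
#'
#' Evaluates, without simulation noise, the per-statement probability of a
#' "true" response for new (`theta_new`) and repeated (`theta_rep`)
#' presentations over a grid of latent plausibility values, together with the
#' truth effect `theta_rep - theta_new` and the two x-axis
#' operationalizations of perceived truth used in this literature: the
#' new-only probability (`perceived_truth_N`) and the new/repeated average
#' (`perceived_truth_mean`).
#'
#' @inheritParams fluency_shift
#' @param p_grid Grid of latent plausibility values (default: -1 to 2 in
#'   steps of 0.01, the span conventionally used for these curves).
#' @param link A [link_spec()].
#' @return A tibble with one row per grid point and columns `p`, `theta_new`,
#'   `theta_rep`, `truth_effect`, `perceived_truth_N`, `perceived_truth_mean`.
#' @examples
#' truth_effect_curve("M1", m = 0.4)
#' @export
truth_effect_curve <- function(variant, m, p_grid = seq(-1, 2, by = 0.01),
                               link = link_spec()) {
  if (length(p_grid) == 0L) stop("`p_grid` must be nonempty.", call. = FALSE)
  theta_new <- prob_true_new(p_grid, link)
  theta_rep <- prob_true_rep(variant, p_grid, m, link)
  tibble::tibble(
    p = p_grid,
    theta_new = theta_new,
    theta_rep = theta_rep,
    truth_effect = theta_rep - theta_new,
    perceived_truth_N = theta_new,
    perceived_truth_mean = (theta_rep + theta_new) / 2
  )
}

#' Transform a response probability to another judgment scale
#'
#' Whether repetition and plausibility interact depends on the scale on which
#' the truth effect is measured; this helper maps probabilities to the probit
#' or logit scale (or leaves them untouched).
#'
#' @param theta Probability (vectorized). Must lie strictly in (0, 1) for the
#'   probit and logit targets.
#' @param target `"probability"`, `"probit"` or `"logit"`.
#' @return Transformed values.
#' @examples
#' transform_scale(0.5, "probit")
#' @export
transform_scale <- function(theta, target = c("probability", "probit", "logit")) {
  target <- match.arg(target)
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("`theta` must be finite numeric.", call. = FALSE)
  }
  if (target == "probability") return(theta)
  if (any(theta <= 0 | theta >= 1)) {
    stop("`theta` must lie strictly in (0, 1) for the ", target, " scale.",
         call. = FALSE)
  }
  switch(target,
    probit = qnorm(theta),
    logit = log(theta / (1 - theta))
  )
}

#' Plot analytic truth-effect curves
#'
#' @param variants Variants to draw, any subset of `"M1"`..`"M4"`.
#' @param m Shift magnitudes; curves are drawn for each (variant, m) pair.
#' @param x_mode x-axis operationalization: new/repeated average or new-only.
#' @param link A [link_spec()].
#' @return A ggplot object.
#' @export
plot_truth_effect_curves <- function(variants = model_variants(),
                                     m = c(0.1, 0.2, 0.4),
                                     x_mode = c("mean_RN", "new_only"),
                                     link = link_spec()) {
  x_mode <- match.arg(x_mode)
  grid <- tidyr::expand_grid(variant = vapply(variants, as_variant, ""), m = m)
  curves <- purrr::pmap_dfr(grid, function(variant, m) {
    dplyr::mutate(truth_effect_curve(variant, m, link = link),
                  variant = variant, m = m)
  })
  xcol <- if (x_mode == "mean_RN") "perceived_truth_mean" else "perceived_truth_N"
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data[[xcol]], y = .data$truth_effect,
    colour = factor(.data$m), group = interaction(.data$variant, .data$m)
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variant, nrow = 1) +
    ggplot2::labs(
      x = if (x_mode == "mean_RN") "perceived truth (R + N)/2" else "perceived truth (N)",
      y = "truth effect (R - N)", colour = "m"
    ) +
    ggplot2::theme_minimal()
}
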