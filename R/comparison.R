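#' Bayes factor from two log marginal likelihoods
#'
#' @param lml_a,lml_b Log marginal likelihoods.
#' @param log Return the log Bayes factor (avoids overflow for well-separated
#'   models).
#' @return `exp(lml_a - lml_b)` (or the difference itself if `log = TRUE`).
#' @examples
#' bayes_factor(-100, -100 + log(10)) # 0.1
#' @export
bayes_factor <- function(lml_a, lml_b, log = FALSE) {
  stopifnot(is.finite(lml_a), is.finite(lml_b))
  if (log) lml_a - lml_b else exp(lml_a - lml_b)
}

#' Posterior model probabilities from log marginal likelihoods
#'
#' Softmax of `lml + log(prior)` with log-sum-exp stabilization.
#'
#' @param lmls Named numeric vector of log marginal likelihoods.
#' @param prior_probs Prior model probabilities (default uniform); must sum
#'   to 1.
#' @return Numeric vector summing to 1 (names preserved).
#' @examples
#' posterior_model_probs(c(M1 = -100, M2 = -103, M3 = -110, M4 = -104))
#' @export
posterior_model_probs <- function(lmls, prior_probs = NULL) {
  k <- length(lmls)
  if (is.null(prior_probs)) prior_probs <- rep(1 / k, k)
  if (length(prior_probs) != k || any(prior_probs < 0) ||
      abs(sum(prior_probs) - 1) > 1e-8) {
    stop("`prior_probs` must be a probability simplex of length ", k, ".",
         call. = FALSE)
  }
  lw <- lmls + log(prior_probs)
  probs <- exp(lw - log_sum_exp(lw))
  probs <- probs / sum(probs)
  names(probs) <- names(lmls)
  probs
}

#' Compare fitted model variants
#'
#' Computes the log marginal likelihood of every fit by bridge sampling
#' (and/or PSIS-LOO ELPD), pairwise Bayes factors, and posterior model
#' probabilities under supplied prior probabilities. All fits must be of the
#' same data.
#'
#' @param fits Named list of `truth_fit` objects (names default to the
#'   variants).
#' @param method `"bridge"`, `"loo"` or `"both"`.
#' @param prior_probs Prior model probabilities (default uniform).
#' @param seed Seed for the bridge proposal draws.
#' @return A `comparison_result`: list with tibbles `lml` (variant, lml,
#'   mc_error), `post_prob`, matrices `bf_log`/`bf`, and (for loo methods)
#'   `elpd` plus pairwise `elpd_diffs`.
#' @export
compare_models <- function(fits, method = c("bridge", "loo", "both"),
                           prior_probs = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.list(fits), length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "truth_fit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$variant, "")
  }
  fingerprints <- unique(vapply(fits, function(f) f$data_fingerprint, ""))
  if (length(fingerprints) > 1) {
    stop("All fits must be of the same dataset.", call. = FALSE)
  }
  out <- list(method = method)

  if (method %in% c("bridge", "both")) {
    lml <- purrr::imap_dfr(fits, function(f, nm) {
      b <- log_marginal_likelihood(f, seed = seed + match(nm, names(fits)))
      tibble::tibble(variant = nm, lml = b$logml, mc_error = b$mc_error,
                     bridge_converged = b$converged)
    })
    lmls <- setNames(lml$lml, lml$variant)
    k <- length(lmls)
    bf_log <- outer(lmls, lmls, `-`)
    dimnames(bf_log) <- list(names(lmls), names(lmls))
    probs <- posterior_model_probs(lmls, prior_probs)
    out$lml <- lml
    out$bf_log <- bf_log
    out$bf <- exp(bf_log)
    out$post_prob <- tibble::tibble(variant = names(probs),
                                    probability = unname(probs))
  }

  if (method %in% c("loo", "both")) {
    loos <- purrr::map(fits, loo_elpd)
    out$elpd <- purrr::imap_dfr(loos, function(l, nm) {
      tibble::tibble(variant = nm, elpd = l$elpd, se = l$se,
                     n_bad_k = l$n_bad_k)
    })
    best <- names(loos)[which.max(out$elpd$elpd)]
    out$elpd_diffs <- purrr::imap_dfr(loos, function(l, nm) {
      d <- elpd_diff(l, loos[[best]])
      tibble::tibble(variant = nm, best = best,
                     elpd_diff = d$elpd_diff, se_diff = d$se_diff)
    })
    out$loos <- loos
  }
  structure(out, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> method:", x$method, "\n")
  if (!is.null(x$lml)) {
    cat("log marginal likelihoods:\n")
    print(as.data.frame(x$lml), row.names = FALSE)
    cat("posterior model probabilities:\n")
    print(as.data.frame(x$post_prob), row.names = FALSE)
  }
  if (!is.null(x$elpd)) {
    cat("PSIS-LOO ELPD:\n")
    print(as.data.frame(x$elpd), row.names = FALSE)
  }
  invisible(x)
}

#' @method tidy comparison_result
#' @export
tidy.comparison_result <- function(x, ...) {
  out <- x$lml %||% tibble::tibble(variant = x$elpd$variant)
  if (!is.null(x$post_prob)) {
    out <- dplyr::left_join(out, x$post_prob, by = "variant")
  }
  if (!is.null(x$elpd)) {
    out <- dplyr::left_join(out, x$elpd, by = "variant")
  }
  out
}

#' @method glance comparison_result
#' @export
glance.comparison_result <- function(x, ...) {
  best_bridge <- if (!is.null(x$post_prob))
    x$post_prob$variant[which.max(x$post_prob$probability)] else NA_character_
  best_loo <- if (!is.null(x$elpd))
    x$elpd$variant[which.max(x$elpd$elpd)] else NA_character_
  tibble::tibble(
    method = x$method, n_models = length(x$lml$variant %||% x$elpd$variant),
    best_bridge = best_bridge,
    max_probability = if (!is.null(x$post_prob)) max(x$post_prob$probability) else NA_real_,
    best_loo = best_loo
  )
}

#' Bar plot of posterior model probabilities
#'
#' @param object A `comparison_result` (bridge or both).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comparison_result
#' @export
autoplot.comparison_result <- function(object, ...) {
  if (is.null(object$post_prob)) {
    stop("No posterior model probabilities (method = 'loo').", call. = FALSE)
  }
  ggplot2::ggplot(object$post_prob,
                  ggplot2::aes(x = .data$variant, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior model probability") +
    ggplot2::theme_minimal()
}
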