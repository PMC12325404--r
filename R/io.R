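trial_columns <- c("participant_id", "statement_id", "repeated", "judgment")

#' Validate a trial table
#'
#' Checks the long-format contract used throughout the package: columns
#' `participant_id`, `statement_id`, `repeated`, `judgment`; strictly binary
#' `repeated`/`judgment`; at most one row per (participant, statement) pair.
#'
#' @param trials A data frame.
#' @param allow_empty Whether a zero-row table is acceptable.
#' @return `trials`, invisibly, as a tibble.
#' @export
validate_trials <- function(trials, allow_empty = FALSE) {
  if (!is.data.frame(trials)) stop("`trials` must be a data frame.", call. = FALSE)
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    stop("`trials` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0) {
    if (allow_empty) return(invisible(tibble::as_tibble(trials)))
    stop("`trials` has zero rows.", call. = FALSE)
  }
  for (col in c("repeated", "judgment")) {
    bad <- which(!trials[[col]] %in% c(0, 1))
    if (length(bad) > 0) {
      stop("Non-binary `", col, "` value at row ", bad[1], ".", call. = FALSE)
    }
  }
  dup <- duplicated(trials[c("participant_id", "statement_id")])
  if (any(dup)) {
    stop("Duplicate (participant, statement) pair at row ", which(dup)[1], ".",
         call. = FALSE)
  }
  invisible(tibble::as_tibble(trials))
}

#' Read a trial table from CSV
#'
#' Expects a header with columns `participant_id`, `statement_id`,
#' `repeated`, `judgment` and validates the binary/uniqueness contract,
#' naming the offending row on failure.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trials(trials)
  tibble::as_tibble(trials)
}

#' Write a trial table to CSV
#'
#' @param trials A trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Generate small bundled example datasets
#'
#' Produces a named list of seeded, reproducible trial tables: one small
#' simulated dataset per model variant (20 statements x 40 participants,
#' `m = 0.4`) plus a hand-checkable 2-statement toy table. Intended for
#' examples and tests; regenerating with the same seed yields identical
#' tables.
#'
#' @param seed Integer seed.
#' @return Named list of tibbles: `M1`, `M2`, `M3`, `M4`, `toy`.
#' @export
make_fixtures <- function(seed = 20250101L) {
  fixtures <- purrr::map(setNames(model_variants(), model_variants()), function(v) {
    set.seed(seed + match(v, model_variants()))
    d <- design_spec(n_statements = 20, n_participants = 40)
    simulate_trials(d, draw_parameters(d, v, m = 0.4))
  })
  fixtures$toy <- tibble::tibble(
    participant_id = rep(1:4, each = 2),
    statement_id = rep(1:2, times = 4),
    repeated = c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L),
    judgment = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L)
  )
  fixtures
}

#' Run a configured analysis pipeline
#'
#' Thin orchestration over the package's building blocks, driven by a config
#' list (or a JSON/YAML file path): simulate a dataset (or read one from
#' CSV), fit one or more model variants, compare them, and write JSON
#' results plus CSV posterior summaries under `out_dir`.
#'
#' Config entries (all optional unless noted): `seed` (required), `variants`
#' (default all four), `design` (arguments to [design_spec()]),
#' `generate` (list `variant`, `m` — if absent, `data_csv` must point at a
#' trial CSV), `mcmc` (arguments to [mcmc_settings()]), `priors` (arguments
#' to [prior_spec()], minus the variant), `compare` (`"bridge"`, `"loo"`, or
#' `"both"`; default `"bridge"`).
#'
#' @param config A named list, or path to a JSON/YAML config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fits, the comparison and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must supply a `seed`.", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  design <- do.call(design_spec, as.list(config$design %||% list()))
  set.seed(config$seed)
  if (!is.null(config$generate)) {
    params <- draw_parameters(design, config$generate$variant,
                              config$generate$m)
    trials <- simulate_trials(design, params)
  } else if (!is.null(config$data_csv)) {
    trials <- read_trials(config$data_csv)
  } else {
    stop("config needs either `generate` or `data_csv`.", call. = FALSE)
  }
  write_trials(trials, file.path(out_dir, "trials.csv"))

  variants <- vapply(config$variants %||% model_variants(), as_variant, "")
  mcmc <- do.call(mcmc_settings, c(as.list(config$mcmc %||% list()),
                                   list(seed = config$seed)))
  fits <- purrr::map(setNames(variants, variants), function(v) {
    pr <- do.call(prior_spec, c(list(variant = v), as.list(config$priors %||% list())))
    fit <- fit_truth_model(trials, v, priors = pr, settings = mcmc)
    readr::write_csv(posterior_summary(fit),
                     file.path(out_dir, paste0("posterior_", v, ".csv")),
                     progress = FALSE)
    hyper <- c("m", "mu_p", "sigma_p", "sigma_u", "sigma_v")
    draws <- tibble::as_tibble(as.data.frame(fit$draws[, hyper, drop = FALSE]))
    draws$chain <- fit$chain_id
    readr::write_csv(draws,
                     file.path(out_dir, paste0("posterior_draws_", v, ".csv.gz")),
                     progress = FALSE)
    fit
  })

  comparison <- NULL
  if (length(fits) > 1L) {
    method <- config$compare %||% "bridge"
    comparison <- compare_models(fits, method = method, seed = config$seed + 1L)
    jsonlite::write_json(
      comparison_to_list(comparison),
      file.path(out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  log_lines <- c(
    paste0("truthfx ", as.character(utils::packageVersion("truthfx"))),
    paste0("seed: ", config$seed),
    paste0("variants: ", paste(variants, collapse = ",")),
    paste0("n_trials: ", nrow(trials)),
    paste0("max_rhat: ", signif(max(purrr::map_dbl(
      fits, ~ max(diagnostics(.x)$rhat, na.rm = TRUE))), 4))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(trials = trials, fits = fits, comparison = comparison,
                 out_dir = out_dir))
}

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the `yaml` package.", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

comparison_to_list <- function(comparison) {
  out <- list(models = as.list(setNames(comparison$lml$lml, comparison$lml$variant)))
  out$log_bayes_factors <- comparison$bf_log
  out$bayes_factors <- comparison$bf
  out$posterior_model_probs <- as.list(
    setNames(comparison$post_prob$probability, comparison$post_prob$variant)
  )
  if (!is.null(comparison$elpd)) {
    out$elpd <- as.list(setNames(comparison$elpd$elpd, comparison$elpd$variant))
  }
  out
}

#' Reanalysis workflow for an external truth-judgment dataset
#'
#' Full-scale route for reanalyzing a deposited dataset: map its columns to
#' the package's trial schema, fit all four model variants, and compare them
#' by bridge-sampling Bayes factors (and optionally PSIS-LOO). The column
#' mapping is user-configured because deposited layouts differ; `mapping`
#' names the source columns holding participant, statement, repetition and
#' judgment.
#'
#' @param data_csv Path to the deposited trial-level CSV.
#' @param mapping Named character vector with entries `participant_id`,
#'   `statement_id`, `repeated`, `judgment` giving the source column names.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param settings [mcmc_settings()]; defaults to the full-scale profile
#'   (8 chains, 1,000 warmup, 10,000 draws).
#' @param method Comparison method passed to [compare_models()].
#' @param variants Model variants to fit (default all four).
#' @return Invisibly, the [run_pipeline()]-style result list.
#' @export
reanalysis_pipeline <- function(data_csv, mapping, out_dir, seed,
                                settings = mcmc_settings(), method = "bridge",
                                variants = model_variants()) {
  raw <- readr::read_csv(data_csv, show_col_types = FALSE, progress = FALSE)
  needed <- c("participant_id", "statement_id", "repeated", "judgment")
  if (!all(needed %in% names(mapping))) {
    stop("`mapping` must name source columns for: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  trials <- tibble::tibble(
    participant_id = raw[[mapping[["participant_id"]]]],
    statement_id = raw[[mapping[["statement_id"]]]],
    repeated = as.integer(raw[[mapping[["repeated"]]]]),
    judgment = as.integer(raw[[mapping[["judgment"]]]])
  )
  validate_trials(trials)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tmp_csv <- file.path(out_dir, "trials_mapped.csv")
  write_trials(trials, tmp_csv)
  run_pipeline(
    config = list(seed = seed, data_csv = tmp_csv, variants = variants,
                  mcmc = settings[c("chains", "warmup", "draws")],
                  compare = method),
    out_dir = out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
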