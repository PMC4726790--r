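# Config-driven orchestration: the surface the command-line script wraps.
# A run configuration is a plain named list (read from YAML or JSON, or
# built inline) that names the model family, its hyperparameters, exactly
# one data source, and the inference settings.

#' Build a validated run configuration
#'
#' @param family `"bernoulli"` or `"normal"`.
#' @param alpha0,beta0 Beta prior shapes (Bernoulli family).
#' @param mu0,tau0_sq,sigma_sq Normal prior mean/variance and known
#'   sampling variance (normal family).
#' @param data Inline observations: numeric vector or 0/1 digit string.
#' @param data_file Path to a one-observation-per-line file.
#' @param generate Generator settings: list with `theta` (or `mean`), `n`,
#'   `seed`.
#' @param psi0 Hypothesized value.
#' @param delta Practically important deviation (bias runs).
#' @param gamma Credible content (default 0.95).
#' @param grid_size Grid cells (default 4096).
#' @param seed Seed for any stochastic path.
#' @param conflict_threshold Advisory prior-data conflict cutoff.
#' @param out Optional output path for the JSON report.
#' @return A validated `rb_config` list.
#' @export
run_config <- function(family = c("bernoulli", "normal"),
                       alpha0 = NULL, beta0 = NULL,
                       mu0 = NULL, tau0_sq = NULL, sigma_sq = NULL,
                       data = NULL, data_file = NULL, generate = NULL,
                       psi0 = NULL, delta = NULL, gamma = 0.95,
                       grid_size = 4096L, seed = NULL,
                       conflict_threshold = 0.05, out = NULL) {
  cfg <- list(family = match.arg(family),
              alpha0 = alpha0, beta0 = beta0,
              mu0 = mu0, tau0_sq = tau0_sq, sigma_sq = sigma_sq,
              data = data, data_file = data_file, generate = generate,
              psi0 = psi0, delta = delta, gamma = gamma,
              grid_size = grid_size, seed = seed,
              conflict_threshold = conflict_threshold, out = out)
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks the hyperparameters match the family, that exactly one data
#' source is given, and that a seed accompanies any stochastic path.  The
#' error message names the offending field.
#'
#' @param cfg A named list as produced by [run_config()] or read by
#'   [read_run_config()].
#' @return The configuration, classed `rb_config`, invisibly valid.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$family) || !cfg$family %in% c("bernoulli", "normal"))
    stopf("config field 'family' must be 'bernoulli' or 'normal'")
  if (cfg$family == "bernoulli") {
    if (is.null(cfg$alpha0) || is.null(cfg$beta0))
      stopf("config fields 'alpha0' and 'beta0' are required for the bernoulli family")
  } else {
    for (f in c("mu0", "tau0_sq", "sigma_sq"))
      if (is.null(cfg[[f]]))
        stopf("config field '%s' is required for the normal family", f)
  }
  nsrc <- sum(!is.null(cfg$data), !is.null(cfg$data_file), !is.null(cfg$generate))
  if (nsrc > 1L)
    stopf("config must name at most one data source among 'data', 'data_file', 'generate'")
  if (!is.null(cfg$generate)) {
    if (is.null(cfg$generate$n)) stopf("config field 'generate$n' is required")
    if (is.null(cfg$generate$seed) && is.null(cfg$seed))
      stopf("config field 'seed' is required when data are generated")
  }
  cfg$gamma <- cfg$gamma %||% 0.95
  cfg$grid_size <- cfg$grid_size %||% 4096L
  cfg$conflict_threshold <- cfg$conflict_threshold %||% 0.05
  structure(cfg, class = "rb_config")
}

#' Read / write a run configuration (YAML or JSON)
#'
#' The format is chosen by file extension (`.yml`/`.yaml` vs `.json`).
#' A configuration written by [write_run_config()] reproduces the identical
#' run when read back.
#'
#' @param path File path.
#' @return The validated configuration.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' not found", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A validated configuration.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- validate_run_config(unclass(cfg))
  keep <- !vapply(cfg, is.null, TRUE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg[keep], path)
  } else {
    writeLines(jsonlite::toJSON(cfg[keep], auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

# resolve the configured data source to a numeric vector (NULL if none)
.config_data <- function(cfg) {
  if (!is.null(cfg$data)) return(read_observations(cfg$data))
  if (!is.null(cfg$data_file)) return(read_observations(cfg$data_file))
  if (!is.null(cfg$generate)) {
    g <- cfg$generate
    return(generate_data(cfg$family, n = g$n, theta = g$theta,
                         mean = g$mean %||% 0,
                         sigma_sq = g$sigma_sq %||% cfg$sigma_sq %||% 1,
                         seed = g$seed %||% cfg$seed))
  }
  NULL
}

.config_model <- function(cfg, data = NULL) {
  if (cfg$family == "bernoulli") {
    beta_bernoulli(cfg$alpha0, cfg$beta0, data = data)
  } else {
    normal_known_var(cfg$mu0, cfg$tau0_sq, cfg$sigma_sq, data = data)
  }
}

#' Run a full evidence assessment from a configuration
#'
#' Pipeline: resolve the data source, reduce to the minimal sufficient
#' statistic, check for prior-data conflict (a conflict is reported
#' prominently but never blocks inference — checking and inference use
#' different factors of the joint distribution), then assess the evidence
#' for `psi0` with [assess_evidence()].  When `cfg$out` is set the JSON
#' report is written there; identical configurations produce byte-identical
#' JSON.
#'
#' @param cfg An `rb_config` (see [run_config()]).
#' @return The `rb_evidence` report, with the `rb_conflict` check attached
#'   as `$conflict` and the serialized JSON as `$json`.
#' @export
run_assess <- function(cfg) {
  cfg <- validate_run_config(cfg)
  if (is.null(cfg$psi0)) stopf("config field 'psi0' is required for an assessment")
  data <- .config_data(cfg)
  if (is.null(data)) stopf("config must provide a data source for an assessment")
  model <- .config_model(cfg, data)
  conflict <- prior_data_conflict(
    prior_predictive(model),
    t_obs = if (model$family == "bernoulli") model$s else model$xbar,
    threshold = cfg$conflict_threshold)
  ev <- assess_evidence(model, psi0 = cfg$psi0, gamma = cfg$gamma,
                        grid_size = cfg$grid_size)
  if (conflict$verdict == "conflict") {
    ev$warnings <- c(ev$warnings, sprintf(
      "prior-data conflict: predictive tail probability %.4f < %.3g",
      conflict$tail_probability, conflict$threshold))
    warning(ev$warnings[length(ev$warnings)], call. = FALSE)
  }
  ev$conflict <- conflict
  ev$json <- report_json(ev, path = cfg$out)
  ev
}

#' Run a pre-experimental bias analysis from a configuration
#'
#' Computes the bias against `psi0` and the bias in favor at
#' `psi0 +/- delta` for the configured sample size (taken from the data
#' source if one is given, otherwise from `cfg$generate$n` or `cfg$n`).
#'
#' @param cfg An `rb_config` with `psi0` and `delta` set.
#' @return An `rb_bias` report.
#' @export
run_bias <- function(cfg) {
  cfg <- validate_run_config(cfg)
  if (is.null(cfg$psi0) || is.null(cfg$delta))
    stopf("config fields 'psi0' and 'delta' are required for a bias run")
  data <- .config_data(cfg)
  n <- if (!is.null(data)) length(data) else cfg$n %||% cfg$generate$n
  if (is.null(n)) stopf("config must provide a sample size ('n' or a data source)")
  model <- .config_model(cfg)
  bias_report(model, psi0 = cfg$psi0, delta = cfg$delta, n = n)
}

#' Run a sample-size design from a configuration
#'
#' @param cfg An `rb_config` with `psi0`, `delta`, and targets
#'   `max_bias_against`, `max_bias_in_favor` (plus optional `n_max`).
#' @return An `rb_design` report.
#' @export
run_design <- function(cfg) {
  cfg <- validate_run_config(cfg)
  for (f in c("psi0", "delta", "max_bias_against", "max_bias_in_favor"))
    if (is.null(cfg[[f]])) stopf("config field '%s' is required for a design run", f)
  design_sample_size(.config_model(cfg), psi0 = cfg$psi0, delta = cfg$delta,
                     max_bias_against = cfg$max_bias_against,
                     max_bias_in_favor = cfg$max_bias_in_favor,
                     n_max = cfg$n_max %||% 500L)
}

#' Run a prior-data conflict check from a configuration
#'
#' @param cfg An `rb_config` with a data source.
#' @return An `rb_conflict` report.
#' @export
run_check <- function(cfg) {
  cfg <- validate_run_config(cfg)
  data <- .config_data(cfg)
  if (is.null(data)) stopf("config must provide a data source for a check")
  model <- .config_model(cfg, data)
  prior_data_conflict(
    prior_predictive(model),
    t_obs = if (model$family == "bernoulli") model$s else model$xbar,
    threshold = cfg$conflict_threshold)
}
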