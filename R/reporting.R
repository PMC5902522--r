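#' Validated analysis configuration
#'
#' Builds the configuration for one of the report commands ([pa_update()],
#' [pa_table()], [pa_check()], [pa_simulate()]), rejecting unknown keys
#' before any computation runs. Probabilities are decimal fractions in
#' \[0, 1\]; percentage strings are rejected.
#'
#' @param command One of `"update"`, `"table"`, `"check"`, `"simulate"`.
#' @param ... Command parameters (see the corresponding `pa_*` function).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(command = c("update", "table", "check", "simulate"),
                            ...) {
  command <- match.arg(command)
  args <- list(...)
  allowed <- switch(command,
    update = c("prior", "alpha", "power", "beta", "bayes_factor", "decimals"),
    table = c("priors", "powers", "alpha", "decimals", "out_csv", "out_txt"),
    check = c("path", "value_col", "group_col", "sep", "alpha_levene",
              "alpha_t", "center", "prior", "effect_prior", "with_bf",
              "decimals"),
    simulate = c("kind", "p0", "effect_prior", "n1", "n2", "mu1", "mu2",
                 "base_variance", "alpha_assumption", "alpha_primary",
                 "nsim", "seed", "fixed_truth", "out_csv", "out_json"))
  unknown <- setdiff(names(args), allowed)
  if (length(unknown))
    stop_usage("unknown configuration key(s) for '", command, "': ",
               paste(unknown, collapse = ", "))
  for (nm in intersect(names(args),
                       c("prior", "alpha", "power", "beta", "p0",
                         "alpha_levene", "alpha_t", "alpha_assumption",
                         "alpha_primary"))) {
    v <- args[[nm]]
    if (is.character(v))
      stop_usage("'", nm, "' must be a decimal fraction, not a string",
                 " (got \"", v, "\")")
  }
  structure(c(list(command = command, schema_version = "1"), args),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json` with a `command`
#'   field and command parameters; validated by [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_data("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_usage("config must be a .yaml or .json file: ", path)
  if (is.null(raw$command)) stop_usage("config needs a 'command' field")
  cmd <- raw$command
  raw$command <- NULL
  if (!is.null(raw$effect_prior))
    raw$effect_prior <- effect_prior_from_list(raw$effect_prior)
  do.call(analysis_config, c(list(command = cmd), raw))
}

new_report <- function(fields) structure(fields, class = "report_bundle")

#' @export
print.report_bundle <- function(x, ...) {
  cat("== plausr report:", x$command, "==\n")
  cat("inputs:\n")
  for (nm in names(x$inputs)) {
    v <- x$inputs[[nm]]
    if (is.numeric(v) || is.character(v) || is.logical(v))
      cat("  ", nm, ": ", paste(format(v), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$warnings) && length(x$warnings))
    for (w in x$warnings) cat("warning:", w, "\n")
  if (x$command == "update") {
    cat(sprintf("posterior plausibility of H0: %s\n", format(x$posterior)))
    cat(sprintf("wrong-acceptance complement (1 - posterior): %s\n",
                format(x$wrong_acceptance)))
    if (!is.null(x$odds_factor))
      cat(sprintf("odds update factor: %s\n", format(x$odds_factor)))
  } else if (x$command == "table") {
    print(x$table)
  } else if (x$command == "check") {
    for (tr in x$tests) print(tr)
    cat("gated choice:", x$gated$test_used, "t test ->",
        if (x$gated$outcome == "reject") "reject" else "retain",
        "equal means\n")
    if (!is.null(x$posterior))
      cat(sprintf("posterior plausibility of equal variances (NHST pathway): %.4f\n",
                  x$posterior))
    if (!is.null(x$bayes_factor))
      cat(sprintf("Bayes factor for equal variances: %.4f -> posterior %.4f\n",
                  x$bayes_factor, x$posterior_bf))
  } else if (x$command == "simulate") {
    print(x$summary)
    if (!is.null(x$out_csv)) cat("written:", x$out_csv, "\n")
    if (!is.null(x$out_json)) cat("written:", x$out_json, "\n")
  }
  invisible(x)
}

default_or <- function(x, default) if (is.null(x)) default else x

#' Update the plausibility of an assumption (report command)
#'
#' Dispatches to the closed-form updating rules: given `alpha` and either
#' `power` or `beta`, the posterior after a nonsignificant check; given
#' `bayes_factor`, the Bayes-factor update. Exactly one pathway must be
#' specified. Defaulted parameters are echoed in the report.
#'
#' @param config An `analysis_config` for command `"update"`, or `NULL` to
#'   build one from `...`.
#' @param ... Parameters forwarded to [analysis_config()].
#' @return A `report_bundle` with the posterior, its wrong-acceptance
#'   complement, the odds factor (NHST pathway), and any warnings.
#' @examples
#' pa_update(prior = 0.1, bayes_factor = 1.070)
#' @export
pa_update <- function(config = NULL, ...) {
  if (is.null(config)) config <- analysis_config("update", ...)
  stopifnot(identical(config$command, "update"))
  if (is.null(config$prior)) stop_usage("'prior' is required")
  has_nhst <- !is.null(config$power) || !is.null(config$beta)
  has_bf <- !is.null(config$bayes_factor)
  if (!is.null(config$power) && !is.null(config$beta))
    stop_usage("supply exactly one of 'power' or 'beta'")
  if (has_nhst && has_bf)
    stop_usage("supply either an NHST pathway (alpha + power/beta) or a ",
               "Bayes factor, not both")
  if (!has_nhst && !has_bf)
    stop_usage("supply alpha + power (or beta), or a Bayes factor")
  prior <- plausibility_prior(config$prior)
  warnings <- character()
  decimals <- default_or(config$decimals, 4)
  if (has_bf) {
    post <- posterior_from_bayes_factor(prior, config$bayes_factor)
    odds <- config$bayes_factor
    inputs <- list(prior = prior$p0, bayes_factor = config$bayes_factor,
                   decimals = decimals)
  } else {
    alpha <- default_or(config$alpha, 0.05)
    beta <- if (!is.null(config$beta)) config$beta else 1 - config$power
    oc <- operating_characteristics(alpha, beta)
    if (!oc$informative)
      warnings <- c(warnings, sprintf(
        "uninformative test: 1 - alpha <= beta (power %s <= alpha %s); %s",
        format(oc$power), format(alpha),
        "a nonrejection does not raise the plausibility of H0"))
    post <- posterior_after_nonrejection(prior, oc)
    odds <- if (oc$beta == 0) Inf else (1 - oc$alpha) / oc$beta
    inputs <- list(prior = prior$p0, alpha = alpha, beta = beta,
                   power = 1 - beta, decimals = decimals)
  }
  new_report(list(command = "update", inputs = inputs,
                  posterior = round_half_up(post$value, decimals),
                  wrong_acceptance = round_half_up(1 - post$value, decimals),
                  odds_factor = odds, warnings = warnings))
}

#' Wrong-acceptance table (report command)
#'
#' Builds the wrong-acceptance table; the defaults reproduce the canonical
#' grid of priors \{.01, .10, .20, .50, .80, .90\} by powers
#' \{.20, .50, .80, .90, .99\} at alpha = .05, rounded to 2 decimals.
#'
#' @inheritParams pa_update
#' @return A `report_bundle` carrying the `wrong_acceptance_table`; when
#'   `out_csv`/`out_txt` paths are configured the table is also written.
#' @export
pa_table <- function(config = NULL, ...) {
  if (is.null(config)) config <- analysis_config("table", ...)
  stopifnot(identical(config$command, "table"))
  priors <- default_or(config$priors, c(.01, .10, .20, .50, .80, .90))
  powers <- default_or(config$powers, c(.20, .50, .80, .90, .99))
  alpha <- default_or(config$alpha, 0.05)
  decimals <- default_or(config$decimals, 2)
  tab <- build_wrong_acceptance_table(priors, powers, alpha, decimals)
  if (!is.null(config$out_csv))
    utils::write.csv(as.data.frame(tab), config$out_csv, row.names = FALSE)
  if (!is.null(config$out_txt)) {
    con <- file(config$out_txt, "w")
    sink(con); print(tab); sink(); close(con)
  }
  new_report(list(command = "table",
                  inputs = list(priors = priors, powers = powers,
                                alpha = alpha, decimals = decimals),
                  table = tab, warnings = character()))
}

#' Check the equal-variances assumption on a data file (report command)
#'
#' Runs Levene's, Student's and Welch's tests on a two-group CSV/TSV file,
#' reports the gated Levene-then-t choice, and — when a prior plausibility is
#' supplied — the posterior plausibility of equal variances via the NHST
#' pathway (catch-all power from the effect prior at the observed group
#' sizes) and optionally via the in-package Bayes factor.
#'
#' @inheritParams pa_update
#' @return A `report_bundle` with the three test results, the gated record,
#'   and posterior plausibilities when a prior was given.
#' @export
pa_check <- function(config = NULL, ...) {
  if (is.null(config)) config <- analysis_config("check", ...)
  stopifnot(identical(config$command, "check"))
  if (is.null(config$path)) stop_usage("'path' to a data file is required")
  sample <- read_two_group(config$path,
                           value_col = default_or(config$value_col, "value"),
                           group_col = default_or(config$group_col, "group"),
                           sep = config$sep)
  alpha_levene <- default_or(config$alpha_levene, 0.05)
  alpha_t <- default_or(config$alpha_t, 0.05)
  center <- default_or(config$center, "mean")
  decimals <- default_or(config$decimals, 4)
  tests <- list(levene = levene_test(sample, center),
                student = student_t(sample),
                welch = welch_t(sample))
  gated <- run_gated_ttest(sample, alpha_levene, alpha_t, center)
  out <- list(command = "check",
              inputs = list(path = config$path, alpha_levene = alpha_levene,
                            alpha_t = alpha_t, center = center,
                            n1 = length(sample$group1), n2 = length(sample$group2),
                            decimals = decimals),
              tests = tests, gated = gated, warnings = character())
  if (!is.null(config$prior)) {
    eff <- default_or(config$effect_prior, effect_prior_lognormal())
    cv <- power_curve("variance_ratio_F", length(sample$group1),
                      length(sample$group2), alpha_levene)
    beta_j <- 1 - integrate_power_over_prior(cv, eff)
    post <- if (decide(tests$levene$p_value, alpha_levene)$outcome == "nonreject")
      posterior_after_nonrejection(config$prior, alpha = alpha_levene, beta = beta_j)
    else posterior_after_rejection(config$prior, alpha = alpha_levene, beta = beta_j)
    out$beta_catch_all <- beta_j
    out$posterior <- post$value
    if (isTRUE(config$with_bf)) {
      out$bayes_factor <- bf_equal_variances(sample, eff)
      out$posterior_bf <- posterior_from_bayes_factor(config$prior,
                                                      out$bayes_factor)$value
    }
  }
  new_report(out)
}

#' Run a simulation scenario (report command)
#'
#' Dispatches to [estimate_wrong_acceptance_rate()] (`kind =
#' "wrong_acceptance"`) or [estimate_gated_type1()] (`kind = "gated_type1"`)
#' and optionally writes the summary as CSV plus a JSON sidecar carrying the
#' seed, the scenario, and standard errors. Identical configurations produce
#' byte-identical CSV output.
#'
#' @inheritParams pa_update
#' @return A `report_bundle` with the `simulation_summary`.
#' @export
pa_simulate <- function(config = NULL, ...) {
  if (is.null(config)) config <- analysis_config("simulate", ...)
  stopifnot(identical(config$command, "simulate"))
  kind <- default_or(config$kind, "wrong_acceptance")
  if (!kind %in% c("wrong_acceptance", "gated_type1"))
    stop_usage("kind must be 'wrong_acceptance' or 'gated_type1'")
  spec <- scenario_spec(
    p0 = default_or(config$p0, 0.5),
    effect_prior = default_or(config$effect_prior, effect_prior_lognormal()),
    n1 = default_or(config$n1, 50), n2 = default_or(config$n2, 50),
    mu1 = default_or(config$mu1, 0), mu2 = default_or(config$mu2, 0),
    base_variance = default_or(config$base_variance, 1),
    alpha_assumption = default_or(config$alpha_assumption, 0.05),
    alpha_primary = default_or(config$alpha_primary, 0.05),
    nsim = default_or(config$nsim, 10000),
    seed = default_or(config$seed, 1),
    fixed_truth = default_or(config$fixed_truth, FALSE))
  summary <- if (kind == "wrong_acceptance")
    estimate_wrong_acceptance_rate(spec) else estimate_gated_type1(spec)
  if (!is.null(config$out_csv)) {
    df <- as.data.frame(unclass(summary)[!vapply(unclass(summary), is.null, logical(1)) &
                                           names(unclass(summary)) != "records"])
    utils::write.csv(df, config$out_csv, row.names = FALSE)
  }
  if (!is.null(config$out_json)) {
    side <- list(kind = kind, seed = spec$seed, nsim = spec$nsim,
                 scenario = list(p0 = spec$p0, n1 = spec$n1, n2 = spec$n2,
                                 mu1 = spec$mu1, mu2 = spec$mu2,
                                 base_variance = spec$base_variance,
                                 alpha_assumption = spec$alpha_assumption,
                                 alpha_primary = spec$alpha_primary,
                                 effect_prior = effect_prior_to_list(spec$effect_prior)),
                 summary = unclass(summary)[setdiff(names(unclass(summary)), "records")])
    jsonlite::write_json(side, config$out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  new_report(list(command = "simulate",
                  inputs = list(kind = kind, p0 = spec$p0, n1 = spec$n1,
                                n2 = spec$n2, nsim = spec$nsim, seed = spec$seed,
                                alpha_assumption = spec$alpha_assumption,
                                alpha_primary = spec$alpha_primary),
                  summary = summary,
                  out_csv = config$out_csv, out_json = config$out_json,
                  warnings = character()))
}
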