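#' Generate a Gaussian two-group sample
#'
#' Seeded synthetic data for the equal-variances workflow: independent
#' Gaussian draws per group with specified means and variances.
#'
#' @param n1,n2 Group sizes.
#' @param mu1,mu2 Group means.
#' @param var1,var2 Group variances (positive); `var1 / var2` is the
#'   variance ratio delta.
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   sample exactly.
#' @return A [two_group_sample()].
#' @examples
#' generate_two_group(10, 10, 0, 0, var1 = 4, var2 = 1, seed = 7)
#' @export
generate_two_group <- function(n1, n2, mu1 = 0, mu2 = 0, var1 = 1, var2 = 1,
                               seed = 1) {
  if (!is.finite(var1) || !is.finite(var2) || var1 <= 0 || var2 <= 0)
    stop_domain("variances must be positive and finite")
  if (n1 < 2 || n2 < 2) stop_domain("group sizes must be at least 2")
  with_seed(seed, two_group_sample(
    stats::rnorm(n1, mu1, sqrt(var1)),
    stats::rnorm(n2, mu2, sqrt(var2))))
}

#' Run the gated Levene-then-t workflow on one sample
#'
#' The common two-stage practice: check equal variances with Levene's test;
#' if the check is nonsignificant use Student's pooled t test for the mean
#' comparison, otherwise switch to Welch's test.
#'
#' @param sample A [two_group_sample()].
#' @param alpha_levene Significance level of the assumption check.
#' @param alpha_t Significance level of the mean comparison.
#' @param center Centering for the Levene statistic.
#' @return A list of class `gated_record`: `levene_p`, `test_used`
#'   (`"student"` or `"welch"`), `primary_p`, and `outcome` of the mean
#'   comparison (`"reject"`/`"nonreject"`).
#' @export
run_gated_ttest <- function(sample, alpha_levene = 0.05, alpha_t = 0.05,
                            center = c("mean", "median")) {
  center <- match.arg(center)
  lev <- levene_test(sample, center)
  gate <- decide(lev$p_value, alpha_levene)
  primary <- if (gate$outcome == "nonreject") student_t(sample) else welch_t(sample)
  structure(list(levene_p = lev$p_value,
                 test_used = if (gate$outcome == "nonreject") "student" else "welch",
                 primary_p = primary$p_value,
                 outcome = decide(primary$p_value, alpha_t)$outcome),
            class = "gated_record")
}

#' @export
print.gated_record <- function(x, ...) {
  cat(sprintf("Levene p = %.4g -> %s t: p = %.4g, %s H0 (equal means)\n",
              x$levene_p, x$test_used, x$primary_p,
              if (x$outcome == "reject") "reject" else "retain"))
  invisible(x)
}

#' Simulation scenario for the assumption-checking workflow
#'
#' Full specification of a hierarchical Monte Carlo scenario: with
#' probability `p0` a replicate's truth is the null (delta = 1); otherwise a
#' variance ratio is drawn from `effect_prior`. Gaussian data are then
#' generated and the assumption check (and, in gated scenarios, the mean
#' comparison) applied.
#'
#' @param p0 Prior probability that the equal-variances null is true. Values
#'   0 or 1 are only allowed with `fixed_truth = TRUE` (a scenario whose
#'   truth is known by construction).
#' @param effect_prior An `effect_prior` over violations.
#' @param n1,n2 Group sizes.
#' @param mu1,mu2 Group means.
#' @param base_variance Variance of group 2; group 1 has
#'   `base_variance * delta`.
#' @param alpha_assumption Level of the Levene check.
#' @param alpha_primary Level of the t test in gated scenarios.
#' @param nsim Number of replicates, at least 100.
#' @param seed Master seed.
#' @param fixed_truth Allow degenerate `p0` in \{0, 1\}.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(p0 = 0.5, effect_prior = effect_prior_lognormal(),
                          n1 = 50, n2 = 50, mu1 = 0, mu2 = 0,
                          base_variance = 1, alpha_assumption = 0.05,
                          alpha_primary = 0.05, nsim = 10000, seed = 1,
                          fixed_truth = FALSE) {
  if (!fixed_truth && (p0 <= 0 || p0 >= 1))
    stop_domain("p0 must be strictly in (0, 1); use fixed_truth = TRUE for a ",
                "known-truth scenario")
  check_prob(p0, "p0")
  stopifnot(inherits(effect_prior, "effect_prior"))
  if (n1 < 2 || n2 < 2) stop_domain("group sizes must be at least 2")
  if (base_variance <= 0) stop_domain("base_variance must be positive")
  check_prob(alpha_assumption, "alpha_assumption", open_left = TRUE, open_right = TRUE)
  check_prob(alpha_primary, "alpha_primary", open_left = TRUE, open_right = TRUE)
  if (nsim < 100) stop_domain("nsim must be at least 100")
  structure(list(p0 = p0, effect_prior = effect_prior, n1 = n1, n2 = n2,
                 mu1 = mu1, mu2 = mu2, base_variance = base_variance,
                 alpha_assumption = alpha_assumption,
                 alpha_primary = alpha_primary, nsim = as.integer(nsim),
                 seed = as.integer(seed), fixed_truth = fixed_truth),
            class = "scenario_spec")
}

# Draw the per-replicate truths and data matrices for a scenario.
simulate_scenario_data <- function(spec) {
  with_seed(spec$seed, {
    is_h0 <- stats::runif(spec$nsim) < spec$p0
    delta <- rep(1, spec$nsim)
    n_alt <- sum(!is_h0)
    if (n_alt > 0) delta[!is_h0] <- sample_delta(spec$effect_prior, n_alt)
    x1 <- matrix(stats::rnorm(spec$n1 * spec$nsim), spec$n1)
    x2 <- matrix(stats::rnorm(spec$n2 * spec$nsim), spec$n2)
    x1 <- sweep(x1, 2, sqrt(spec$base_variance * delta), `*`) + spec$mu1
    x2 <- x2 * sqrt(spec$base_variance) + spec$mu2
    list(is_h0 = is_h0, delta = delta, x1 = x1, x2 = x2)
  })
}

new_simulation_summary <- function(fields) {
  structure(fields, class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("Monte Carlo summary (", x$kind, ", nsim = ", x$nsim,
      ", seed = ", x$seed, ")\n", sep = "")
  if (identical(x$kind, "wrong_acceptance")) {
    cat(sprintf("  nonrejections: %d of %d; wrong acceptances: %d\n",
                x$n_nonreject, x$nsim, x$n_wrong_acceptances))
    cat(sprintf("  empirical wrong-acceptance rate: %.4f (SE %.4f)\n",
                x$empirical_wrong_acceptance_rate, x$se))
    if (!is.null(x$analytic_prediction))
      cat(sprintf("  analytic prediction: %.4f\n", x$analytic_prediction))
  } else {
    cat(sprintf("  gated rejection rate: %.4f (SE %.4f)\n", x$rate, x$se))
    if (!is.na(x$rate_equal_arm))
      cat(sprintf("  equal-variance arm: %.4f (SE %.4f) over %d replicates\n",
                  x$rate_equal_arm, x$se_equal_arm, x$n_equal_arm))
    if (!is.na(x$rate_unequal_arm))
      cat(sprintf("  unequal-variance arm: %.4f (SE %.4f) over %d replicates\n",
                  x$rate_unequal_arm, x$se_unequal_arm, x$n_unequal_arm))
  }
  invisible(x)
}

#' Empirical wrong-acceptance rate of an assumption check
#'
#' Hierarchical Monte Carlo: each replicate draws a truth (null with
#' probability `p0`, otherwise a violation from the effect prior), generates
#' Gaussian data, and runs the Levene check. The wrong-acceptance rate is the
#' fraction of nonrejections whose truth was a violation — the quantity the
#' analytic posterior (and its complement, the wrong-acceptance proportion)
#' predicts. The analytic prediction uses the catch-all Type II error of the
#' same check at the same group sizes, from its Monte Carlo power curve.
#'
#' @param spec A [scenario_spec()].
#' @param analytic Compute the analytic prediction (costs one power-curve
#'   estimation)?
#' @param keep_records Keep the per-replicate table (truth delta, Levene p,
#'   decision)?
#' @param curve_nsim Replicates for the Levene power curve behind the
#'   analytic prediction.
#' @return A `simulation_summary` with counts, the empirical rate and its
#'   binomial standard error, and the analytic prediction. The rate is `NaN`
#'   (with a warning) if no replicate was nonrejected.
#' @export
estimate_wrong_acceptance_rate <- function(spec, analytic = TRUE,
                                           keep_records = FALSE,
                                           curve_nsim = 20000) {
  stopifnot(inherits(spec, "scenario_spec"))
  sim <- simulate_scenario_data(spec)
  lev_p <- levene_p_matrix(sim$x1, sim$x2, "mean")
  nonreject <- lev_p >= spec$alpha_assumption
  n_non <- sum(nonreject)
  n_wrong <- sum(nonreject & !sim$is_h0)
  if (n_non == 0) {
    warn_class("no nonrejections: wrong-acceptance rate undefined",
               "plausr_undefined_rate")
    rate <- NaN; se <- NaN
  } else {
    rate <- n_wrong / n_non
    se <- sqrt(rate * (1 - rate) / n_non)
  }
  pred <- NULL
  if (analytic) {
    pred <- if (spec$p0 >= 1) 0 else if (spec$p0 <= 0) 1 else {
      cv <- power_curve("levene", spec$n1, spec$n2, spec$alpha_assumption,
                        nsim = curve_nsim, seed = child_seed(spec$seed, 7919))
      beta_j <- 1 - integrate_power_over_prior(cv, spec$effect_prior)
      wrong_acceptance_proportion(spec$p0, spec$alpha_assumption, 1 - beta_j)
    }
  }
  out <- list(kind = "wrong_acceptance", nsim = spec$nsim, seed = spec$seed,
              n_reject = spec$nsim - n_non, n_nonreject = n_non,
              n_wrong_acceptances = n_wrong,
              empirical_wrong_acceptance_rate = rate, se = se,
              analytic_prediction = pred)
  if (keep_records)
    out$records <- data.frame(delta = sim$delta, is_h0 = sim$is_h0,
                              levene_p = lev_p,
                              decision = ifelse(nonreject, "nonreject", "reject"))
  new_simulation_summary(out)
}

#' Size of the gated Levene-then-t procedure
#'
#' Under equal means (`mu1 = mu2`) the rejection rate of the two-stage
#' procedure is its realised Type I error for the mean comparison. The rate
#' is reported overall and separately for replicates whose truth was equal
#' variances and for those whose truth was a violation drawn from the effect
#' prior; the unequal-variance arm is where pretesting distorts the nominal
#' level (the Behrens–Fisher problem).
#'
#' @param spec A [scenario_spec()] with `mu1 == mu2`.
#' @param keep_records Keep the per-replicate table (truth delta, Levene p,
#'   test used, primary p, decision)?
#' @return A `simulation_summary` with overall and per-arm rejection rates
#'   and binomial standard errors.
#' @export
estimate_gated_type1 <- function(spec, keep_records = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$mu1 != spec$mu2)
    stop_domain("gated Type I error requires mu1 == mu2")
  sim <- simulate_scenario_data(spec)
  lev_p <- levene_p_matrix(sim$x1, sim$x2, "mean")
  use_student <- lev_p >= spec$alpha_assumption
  p_student <- student_p_matrix(sim$x1, sim$x2)
  p_welch <- welch_p_matrix(sim$x1, sim$x2)
  primary_p <- ifelse(use_student, p_student, p_welch)
  rejected <- primary_p < spec$alpha_primary
  arm_rate <- function(idx) {
    n <- sum(idx)
    if (n == 0) return(list(rate = NA_real_, se = NA_real_, n = 0L))
    r <- mean(rejected[idx])
    list(rate = r, se = sqrt(r * (1 - r) / n), n = n)
  }
  eq <- arm_rate(sim$is_h0); uneq <- arm_rate(!sim$is_h0)
  out <- list(kind = "gated_type1", nsim = spec$nsim, seed = spec$seed,
              rate = mean(rejected),
              se = sqrt(mean(rejected) * (1 - mean(rejected)) / spec$nsim),
              rate_equal_arm = eq$rate, se_equal_arm = eq$se, n_equal_arm = eq$n,
              rate_unequal_arm = uneq$rate, se_unequal_arm = uneq$se,
              n_unequal_arm = uneq$n)
  if (keep_records)
    out$records <- data.frame(delta = sim$delta, is_h0 = sim$is_h0,
                              levene_p = lev_p,
                              test_used = ifelse(use_student, "student", "welch"),
                              primary_p = primary_p,
                              decision = ifelse(rejected, "reject", "nonreject"))
  new_simulation_summary(out)
}

#' Monte Carlo validation of the wrong-acceptance table
#'
#' For each (prior, power) cell, finds by bisection the variance ratio at
#' which the Levene check attains the target power at the scenario's group
#' sizes, runs the hierarchical simulation with a point-mass violation at
#' that ratio, and compares the empirical wrong-acceptance rate with the
#' analytic table cell.
#'
#' @param priors Prior plausibilities (rows), each strictly in (0, 1).
#' @param powers Target powers (columns).
#' @param alpha Level of the Levene check.
#' @param nsim Replicates per cell (at least 100).
#' @param seed Master seed; cells get derived sub-seeds.
#' @param n1,n2 Group sizes used for power matching and simulation.
#' @param curve_nsim Replicates behind the common-random-numbers Levene
#'   power curve used for the bisection.
#' @return A data frame with one row per cell: the matched `delta` and its
#'   attained power, the empirical rate and SE, the analytic (unrounded) and
#'   printed (2 d.p.) cells, and `within_3se`. Cells whose target power is
#'   unattainable at these group sizes are flagged `attainable = FALSE`.
#' @export
validate_table1 <- function(priors, powers, alpha = 0.05, nsim = 20000,
                            seed = 1, n1 = 50, n2 = 50, curve_nsim = 20000) {
  if (nsim < 100) stop_domain("nsim must be at least 100")
  cv <- power_curve("levene", n1, n2, alpha, nsim = curve_nsim,
                    seed = child_seed(seed, 1))
  rows <- list(); k <- 0L
  for (pw in powers) {
    inv <- invert_power_curve(cv, pw)
    for (p0 in priors) {
      k <- k + 1L
      if (!inv$attainable) {
        rows[[k]] <- data.frame(prior = p0, power = pw, delta = NA_real_,
                                attained_power = NA_real_, attainable = FALSE,
                                empirical = NA_real_, se = NA_real_,
                                analytic = NA_real_, printed = NA_real_,
                                within_3se = NA)
        next
      }
      spec <- scenario_spec(p0 = p0,
                            effect_prior = effect_prior_discrete(inv$delta),
                            n1 = n1, n2 = n2, alpha_assumption = alpha,
                            nsim = nsim, seed = child_seed(seed, 100 + k))
      sim <- estimate_wrong_acceptance_rate(spec, analytic = FALSE)
      analytic <- wrong_acceptance_proportion(p0, alpha, pw)
      printed <- round_half_up(analytic, 2)
      rows[[k]] <- data.frame(
        prior = p0, power = pw, delta = inv$delta,
        attained_power = inv$power, attainable = TRUE,
        empirical = sim$empirical_wrong_acceptance_rate, se = sim$se,
        analytic = analytic, printed = printed,
        within_3se = abs(sim$empirical_wrong_acceptance_rate - printed) <= 3 * sim$se)
    }
  }
  do.call(rbind, rows)
}
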