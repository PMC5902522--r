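#' A set of specific alternatives with powers and prior weights
#'
#' Represents the discrete catch-all hypothesis: a list of specific
#' violations of the assumption (variance ratios `delta != 1`), the power of
#' the check against each, and the analyst's prior weight on each.
#'
#' @param effect Positive variance ratios, all distinct.
#' @param power Rejection probability of the check at each ratio.
#' @param weight Non-negative prior weights (need not be normalised).
#' @return An object of class `alternative_set`.
#' @export
alternative_set <- function(effect, power, weight = rep(1, length(effect))) {
  if (length(effect) == 0L) stop_domain("need at least one alternative")
  if (length(power) != length(effect) || length(weight) != length(effect))
    stop_domain("effect, power and weight must have equal length")
  if (any(effect <= 0) || !all(is.finite(effect)))
    stop_domain("effects (variance ratios) must be positive and finite")
  if (anyDuplicated(effect)) stop_domain("alternative effects must be distinct")
  for (p in power) check_prob(p, "power")
  if (any(weight < 0) || sum(weight) <= 0)
    stop_domain("weights must be non-negative with a positive total")
  structure(list(effect = effect, power = power, weight = weight),
            class = "alternative_set")
}

#' Catch-all Type II error of an assumption check
#'
#' The analyst's overall probability of missing a violation is the
#' prior-weighted average of the per-alternative miss rates:
#' \deqn{\beta_j = \sum_i (1 - \mathrm{power}_i)\, w_i \big/ \sum_i w_i.}
#' It always lies between the smallest and largest per-alternative miss rate,
#' and it is this mixture — not the power against any single alternative —
#' that drives the posterior plausibility of the assumption.
#'
#' @param alts An [alternative_set()].
#' @return The catch-all Type II error, a probability.
#' @examples
#' mixture_type2_error(alternative_set(c(2, 4), power = c(0.6, 0.8)))
#' @export
mixture_type2_error <- function(alts) {
  stopifnot(inherits(alts, "alternative_set"))
  sum((1 - alts$power) * alts$weight) / sum(alts$weight)
}

#' Exact power of the two-sided variance-ratio F test
#'
#' For Gaussian groups with variance ratio `delta`, the sample variance ratio
#' is `delta` times an F(n1-1, n2-1) variate, so the power of the equal-tail
#' two-sided F test has a closed form: the probability that the ratio falls
#' outside the central-F acceptance region at level `alpha`. At `delta = 1`
#' the power equals the size `alpha` exactly.
#'
#' @param delta Variance ratio var1 / var2 (vectorised).
#' @param n1,n2 Group sizes, at least 2.
#' @param alpha Significance level.
#' @return Power values in \[alpha, 1\], same length as `delta`.
#' @examples
#' f_test_variance_power(4, n1 = 21, n2 = 21, alpha = 0.05)
#' @export
f_test_variance_power <- function(delta, n1, n2, alpha = 0.05) {
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop_domain("delta must be positive and finite")
  if (n1 < 2 || n2 < 2) stop_domain("group sizes must be at least 2")
  check_prob(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  d1 <- n1 - 1; d2 <- n2 - 1
  lo <- stats::qf(alpha / 2, d1, d2)
  hi <- stats::qf(1 - alpha / 2, d1, d2)
  stats::pf(lo / delta, d1, d2) + stats::pf(hi / delta, d1, d2, lower.tail = FALSE)
}

#' Monte Carlo power of Levene's test at a specific variance ratio
#'
#' Levene's statistic has no closed-form power function, so the rejection
#' rate against a given `delta` is estimated by simulating Gaussian two-group
#' datasets. Group 1 has variance `delta`, group 2 variance 1.
#'
#' @inheritParams f_test_variance_power
#' @param nsim Number of replicates (at least 100).
#' @param seed Integer seed; the same seed and arguments give the identical
#'   estimate.
#' @param center Centering used by the Levene statistic, `"mean"` (classical)
#'   or `"median"` (Brown–Forsythe).
#' @return A list with `power` (empirical rejection rate) and `se` (binomial
#'   standard error).
#' @export
levene_power_mc <- function(delta, n1, n2, alpha = 0.05, nsim = 10000,
                            seed = 1, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.finite(delta) || delta <= 0) stop_domain("delta must be positive and finite")
  if (nsim < 100) stop_domain("nsim must be at least 100")
  p <- with_seed(seed, {
    x1 <- matrix(stats::rnorm(n1 * nsim, sd = sqrt(delta)), n1)
    x2 <- matrix(stats::rnorm(n2 * nsim), n2)
    levene_p_matrix(x1, x2, center)
  })
  rate <- mean(p < alpha)
  list(power = rate, se = sqrt(rate * (1 - rate) / nsim))
}

#' Power curve of an assumption check over the variance ratio
#'
#' Wraps a test's power function delta -> P(reject | delta) at fixed group
#' sizes and level. The F-ratio curve is exact; the Levene curve is a seeded
#' Monte Carlo estimate evaluated with common random numbers, so it is a
#' deterministic, monotone-in-delta function for a given seed.
#'
#' @param test `"variance_ratio_F"` or `"levene"`.
#' @param n1,n2 Group sizes.
#' @param alpha Significance level.
#' @param nsim Replicates per evaluation for the Levene curve.
#' @param seed Seed for the common random numbers of the Levene curve.
#' @return An object of class `power_curve`; call it on delta values via
#'   `curve$evaluator(delta)`.
#' @export
power_curve <- function(test = c("variance_ratio_F", "levene"), n1, n2,
                        alpha = 0.05, nsim = 20000, seed = 1) {
  test <- match.arg(test)
  if (n1 < 2 || n2 < 2) stop_domain("group sizes must be at least 2")
  check_prob(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  evaluator <- if (test == "variance_ratio_F") {
    function(delta) f_test_variance_power(delta, n1, n2, alpha)
  } else {
    # Common random numbers: one standardized draw set reused for every
    # delta, scaled by sqrt(delta). Same seed => same curve.
    z1 <- with_seed(seed, matrix(stats::rnorm(n1 * nsim), n1))
    z2 <- with_seed(child_seed(seed, 1), matrix(stats::rnorm(n2 * nsim), n2))
    function(delta) {
      vapply(delta, function(d) {
        mean(levene_p_matrix(z1 * sqrt(d), z2, "mean") < alpha)
      }, numeric(1))
    }
  }
  structure(list(test_name = test, n1 = n1, n2 = n2, alpha = alpha,
                 nsim = if (test == "levene") nsim else NA_integer_,
                 seed = if (test == "levene") seed else NA_integer_,
                 evaluator = evaluator),
            class = "power_curve")
}

#' Expected power of a check under an effect prior
#'
#' Integrates a power curve over the violation part of an effect prior:
#' the analyst's assessed power `1 - beta_j` against the catch-all
#' alternative. Any point mass at `delta = 1` is excluded — it belongs to the
#' null, not to the catch-all — and the continuous weights are renormalised
#' accordingly before integration.
#'
#' @param curve A [power_curve()].
#' @param prior An `effect_prior`.
#' @return Expected power, a probability. The catch-all Type II error is one
#'   minus this value.
#' @examples
#' cv <- power_curve("variance_ratio_F", n1 = 21, n2 = 21)
#' 1 - integrate_power_over_prior(cv, effect_prior_lognormal())  # beta_j
#' @export
integrate_power_over_prior <- function(curve, prior) {
  stopifnot(inherits(curve, "power_curve"), inherits(prior, "effect_prior"))
  sum(curve$evaluator(exp(prior$nodes)) * prior$weights)
}

#' Variance ratio at which a check attains a target power
#'
#' Inverts a power curve by bisection on `log(delta) >= 0`: finds the
#' `delta >= 1` whose rejection probability equals `target`. For the Monte
#' Carlo Levene curve the common-random-numbers construction makes the curve
#' deterministic and monotone, so bisection is well behaved.
#'
#' @param curve A [power_curve()].
#' @param target Target power, must exceed the curve's size at `delta = 1`
#'   and be attainable below `delta = exp(log_upper)`.
#' @param tol Acceptable calibration slack: a classed warning is raised when
#'   the attained power misses the target by more than this.
#' @param log_upper Upper end of the bisection bracket on log delta.
#' @return A list with `delta`, the `power` attained there, and `attainable`
#'   (`FALSE`, with `delta = NA`, if the target is outside the bracket).
#' @export
invert_power_curve <- function(curve, target, tol = 0.005, log_upper = 6.9) {
  stopifnot(inherits(curve, "power_curve"))
  check_prob(target, "target")
  lo <- 0; hi <- log_upper
  p_lo <- curve$evaluator(1); p_hi <- curve$evaluator(exp(hi))
  if (target <= p_lo || target > p_hi)
    return(list(delta = NA_real_, power = NA_real_, attainable = FALSE))
  # Converge the bracket fully: the posterior is sensitive to the attained
  # power, so the bisection runs to bracket collapse rather than stopping at
  # the first within-tolerance evaluation.
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    p_mid <- curve$evaluator(exp(mid))
    if (p_mid < target) lo <- mid else hi <- mid
    if (hi - lo < 5e-4) break
  }
  if (abs(p_mid - target) > tol)
    warn_class(sprintf("power calibration off target by %.4f (> tol %.4f)",
                       abs(p_mid - target), tol), "plausr_calibration_warning")
  list(delta = exp(mid), power = p_mid, attainable = TRUE)
}
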