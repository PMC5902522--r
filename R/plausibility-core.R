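#' Prior plausibility of a model assumption
#'
#' Records an analyst's prior probability that a model assumption (the null
#' hypothesis of an assumption check) holds. The prior must lie strictly
#' between 0 and 1: an analyst who already assigns probability 0 or 1 to the
#' assumption has no reason to test it, and the updating formulas degenerate.
#'
#' @param p0 Prior probability that the assumption holds, strictly in (0, 1).
#' @param label Optional free-text description of the assumption.
#' @return An object of class `plausibility_prior`.
#' @examples
#' plausibility_prior(0.1, "equal variances of boys and girls")
#' @export
plausibility_prior <- function(p0, label = "") {
  if (!is.numeric(p0) || length(p0) != 1L || !is.finite(p0))
    stop_domain("p0 must be a single finite number")
  if (p0 <= 0 || p0 >= 1)
    stop_domain("prior plausibility must lie strictly between 0 and 1 ",
                "(a prior of 0 or 1 makes testing the assumption redundant); got ",
                format(p0))
  structure(list(p0 = p0, label = as.character(label)),
            class = "plausibility_prior")
}

#' @export
print.plausibility_prior <- function(x, ...) {
  cat("Prior plausibility P(H0) =", format(x$p0), "\n")
  if (nzchar(x$label)) cat("  assumption:", x$label, "\n")
  invisible(x)
}

as_prior <- function(prior) {
  if (inherits(prior, "plausibility_prior")) return(prior)
  plausibility_prior(prior)
}

#' Operating characteristics of an assumption check
#'
#' Bundles the Type I error rate `alpha` = P(reject | H0) of a test with the
#' analyst's catch-all Type II error `beta` = P(not reject | not H0), the
#' prior-weighted average miss rate over all violations the analyst considers
#' plausible (see [mixture_type2_error()]). The test is *informative* — a
#' nonrejection raises the plausibility of the assumption — exactly when
#' `alpha < 1 - beta`, i.e. when the test rejects violations more often than
#' it falsely rejects the truth.
#'
#' @param alpha Type I error rate, in \[0, 1).
#' @param beta Catch-all Type II error rate, in \[0, 1\].
#' @return An object of class `operating_characteristics` with fields
#'   `alpha`, `beta`, `power` (= 1 - beta) and logical `informative`.
#' @examples
#' operating_characteristics(alpha = 0.05, beta = 0.10)
#' @export
operating_characteristics <- function(alpha, beta) {
  check_prob(alpha, "alpha", open_right = TRUE)
  check_prob(beta, "beta")
  # tolerance absorbs float noise in 1 - beta so that e.g. alpha = .05,
  # beta = .95 is classified as the exactly uninformative boundary
  structure(list(alpha = alpha, beta = beta, power = 1 - beta,
                 informative = (1 - beta) - alpha > 1e-12),
            class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("alpha = %s, beta = %s (power %s) — %s\n",
              format(x$alpha), format(x$beta), format(x$power),
              if (x$informative) "informative"
              else if (x$alpha == x$power) "uninformative (alpha = power)"
              else "anti-informative (alpha > power)"))
  invisible(x)
}

as_oc <- function(oc, alpha = NULL, beta = NULL) {
  if (inherits(oc, "operating_characteristics")) return(oc)
  operating_characteristics(alpha, beta)
}

#' Accept-or-reject decision from a p-value
#'
#' The conventional decision rule of significance testing: reject the null
#' hypothesis when `p_value < alpha`; when `p_value >= alpha` (including
#' exact equality) the null is retained.
#'
#' @param p_value Observed p-value, in \[0, 1\].
#' @param alpha Significance level, strictly in (0, 1).
#' @return An object of class `decision_outcome` with fields `outcome`
#'   (`"reject"` or `"nonreject"`), `p_value` and `alpha`.
#' @examples
#' decide(0.060, 0.05)  # retained
#' decide(0.044, 0.05)  # rejected
#' @export
decide <- function(p_value, alpha) {
  check_prob(p_value, "p_value")
  check_prob(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  structure(list(outcome = if (p_value < alpha) "reject" else "nonreject",
                 p_value = p_value, alpha = alpha),
            class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat(sprintf("p = %s vs alpha = %s: %s H0\n", format(x$p_value),
              format(x$alpha),
              if (x$outcome == "reject") "reject" else "retain"))
  invisible(x)
}

new_posterior <- function(value, conditioned_on, infinite_evidence = FALSE) {
  structure(list(value = value, conditioned_on = conditioned_on,
                 infinite_evidence = infinite_evidence),
            class = "posterior_plausibility")
}

#' @export
print.posterior_plausibility <- function(x, ...) {
  lab <- switch(x$conditioned_on,
                nonrejection = "P(H0 | nonrejection)",
                rejection = "P(H0 | rejection)",
                bayes_factor = "P(H0 | data)")
  cat(lab, "=", format(x$value), "\n")
  if (isTRUE(x$infinite_evidence))
    cat("  (beta = 0: violations are always detected, so a nonrejection is conclusive)\n")
  invisible(x)
}

#' Posterior plausibility after a nonsignificant assumption check
#'
#' Updates a prior plausibility `p0` by Bayes' rule after the assumption check
#' failed to reject, using the test's operating characteristics:
#' \deqn{P(H_0 \mid \neg R) = \frac{p_0 (1-\alpha)}{p_0 (1-\alpha) + (1-p_0)\,\beta}.}
#' When `alpha < 1 - beta` (an informative test) the posterior exceeds the
#' prior; when `alpha = 1 - beta` the test carries no information and the
#' posterior equals the prior. The special case `beta = 0` (every violation is
#' detected) returns 1 and flags infinite evidence: surviving such a check
#' proves the assumption.
#'
#' @param prior A [plausibility_prior()] or a bare probability in (0, 1).
#' @param oc An [operating_characteristics()] object, or `NULL` if `alpha`
#'   and `beta` are given directly.
#' @param alpha,beta Alternative scalar interface to `oc`.
#' @return A `posterior_plausibility` object; its `value` field holds the
#'   posterior probability.
#' @seealso [wrong_acceptance_proportion()] for the complement,
#'   [odds_update_factor_nonrejection()] for the odds form.
#' @examples
#' posterior_after_nonrejection(0.1, alpha = 0.05, beta = 0.10)  # 0.5135
#' @export
posterior_after_nonrejection <- function(prior, oc = NULL, alpha = NULL, beta = NULL) {
  prior <- as_prior(prior)
  oc <- as_oc(oc, alpha, beta)
  p0 <- prior$p0
  if (oc$beta == 0) {
    if (oc$alpha >= 1) stop_domain("degenerate test: alpha = 1 with beta = 0")
    return(new_posterior(1, "nonrejection", infinite_evidence = TRUE))
  }
  num <- p0 * (1 - oc$alpha)
  den <- num + (1 - p0) * oc$beta
  if (den == 0) stop_domain("nonrejection has probability zero under this prior and test")
  new_posterior(num / den, "nonrejection")
}

#' Posterior plausibility after a significant assumption check
#'
#' The Bayes complement of [posterior_after_nonrejection()]: the plausibility
#' that the assumption holds even though the check rejected it,
#' \eqn{p_0 \alpha / (p_0 \alpha + (1-p_0)(1-\beta))}.
#'
#' @inheritParams posterior_after_nonrejection
#' @return A `posterior_plausibility` object.
#' @examples
#' posterior_after_rejection(0.5, alpha = 0.05, beta = 0.10)  # 0.0526
#' @export
posterior_after_rejection <- function(prior, oc = NULL, alpha = NULL, beta = NULL) {
  prior <- as_prior(prior)
  oc <- as_oc(oc, alpha, beta)
  p0 <- prior$p0
  num <- p0 * oc$alpha
  den <- num + (1 - p0) * (1 - oc$beta)
  if (den == 0)
    stop_domain("rejection has probability zero (alpha = 0 and beta = 1); ",
                "posterior after rejection is undefined")
  new_posterior(num / den, "rejection")
}

#' Odds update factor after a nonrejection
#'
#' A nonsignificant assumption check multiplies the prior odds of the
#' assumption against its catch-all complement by `(1 - alpha) / beta`. A
#' factor of 1 (when `alpha = 1 - beta`) means the check was uninformative.
#'
#' @inheritParams posterior_after_nonrejection
#' @return The positive odds factor. When `beta = 0` the factor is infinite;
#'   `Inf` is returned together with a classed warning
#'   (`plausr_infinite_evidence`) rather than overflowing silently.
#' @examples
#' odds_update_factor_nonrejection(alpha = 0.05, beta = 0.10)  # 9.5
#' @export
odds_update_factor_nonrejection <- function(oc = NULL, alpha = NULL, beta = NULL) {
  oc <- as_oc(oc, alpha, beta)
  if (oc$beta == 0) {
    warn_class("beta = 0: nonrejection carries infinite evidence for the assumption",
               "plausr_infinite_evidence")
    return(Inf)
  }
  (1 - oc$alpha) / oc$beta
}

#' Expected proportion of wrong acceptances
#'
#' If an analyst accepts the assumption whenever the check is nonsignificant,
#' the long-run proportion of those acceptances that are wrong is one minus
#' the posterior plausibility after nonrejection. This — not the Type I or
#' Type II rate — is the error rate that matters when an accepted assumption
#' licenses use of a statistical model.
#'
#' @inheritParams posterior_after_nonrejection
#' @param power The assessed power `1 - beta` of the check against the
#'   violations considered plausible.
#' @return The wrong-acceptance proportion in \[0, 1\].
#' @examples
#' wrong_acceptance_proportion(0.10, alpha = 0.05, power = 0.90)  # 0.486...
#' @export
wrong_acceptance_proportion <- function(prior, alpha, power) {
  check_prob(power, "power")
  post <- posterior_after_nonrejection(prior, alpha = alpha, beta = 1 - power)
  1 - post$value
}

#' Table of wrong-acceptance proportions
#'
#' Tabulates [wrong_acceptance_proportion()] over a grid of prior
#' plausibilities (rows) and assessed powers (columns) at a fixed significance
#' level. Even at power .90, an assumption with prior plausibility .10 that
#' survives the check is still wrong about half the time.
#'
#' @param priors Numeric vector of prior plausibilities, each strictly in (0, 1).
#' @param powers Numeric vector of assessed powers, each in \[0, 1\].
#' @param alpha Significance level of the check.
#' @param decimals Number of decimals cells are rounded to (half away from
#'   zero); use `decimals = NULL` for unrounded cells.
#' @return An object of class `wrong_acceptance_table`: a list with the cell
#'   matrix (`cells`, rows named by prior, columns by power) and the inputs.
#' @examples
#' build_wrong_acceptance_table(c(.01, .10, .20, .50, .80, .90),
#'                              c(.20, .50, .80, .90, .99), alpha = 0.05)
#' @export
build_wrong_acceptance_table <- function(priors, powers, alpha = 0.05, decimals = 2) {
  if (length(priors) == 0L || length(powers) == 0L)
    stop_domain("priors and powers must be non-empty")
  for (p in priors) check_prob(p, "prior", open_left = TRUE, open_right = TRUE)
  for (w in powers) check_prob(w, "power")
  cells <- outer(priors, powers,
                 Vectorize(function(p, w) wrong_acceptance_proportion(p, alpha, w)))
  if (!is.null(decimals)) cells <- round_half_up(cells, decimals)
  dimnames(cells) <- list(format(priors), format(powers))
  structure(list(cells = cells, priors = priors, powers = powers,
                 alpha = alpha, decimals = decimals),
            class = "wrong_acceptance_table")
}

#' @export
print.wrong_acceptance_table <- function(x, ...) {
  cat(sprintf("Expected proportion of wrong acceptances of H0 (alpha = %s)\n",
              format(x$alpha)))
  cat("rows: prior plausibility P(H0); columns: assessed power 1 - beta\n")
  print(x$cells)
  invisible(x)
}

#' @export
as.data.frame.wrong_acceptance_table <- function(x, ...) {
  data.frame(prior = rep(x$priors, times = length(x$powers)),
             power = rep(x$powers, each = length(x$priors)),
             wrong_acceptance = as.vector(x$cells))
}

#' Posterior plausibility from a Bayes factor
#'
#' Updates the prior plausibility with a Bayes factor quantifying the support
#' of the data for the assumption over its catch-all complement (`bf > 1`
#' favours the assumption): posterior odds = prior odds times `bf`.
#'
#' @inheritParams posterior_after_nonrejection
#' @param bf Positive Bayes factor for H0 versus its complement.
#' @return A `posterior_plausibility` object.
#' @examples
#' posterior_from_bayes_factor(0.1, 1.070)  # 0.106
#' @export
posterior_from_bayes_factor <- function(prior, bf) {
  prior <- as_prior(prior)
  if (!is.numeric(bf) || length(bf) != 1L || !is.finite(bf) || bf <= 0)
    stop_domain("bf must be a single positive finite number")
  odds <- prior$p0 / (1 - prior$p0) * bf
  new_posterior(odds / (1 + odds), "bayes_factor")
}
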