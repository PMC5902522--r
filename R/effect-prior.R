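#' Priors over violations of the equal-variances assumption
#'
#' An effect prior describes which variance ratios `delta = var1 / var2` an
#' analyst considers plausible *if* the assumption `delta = 1` is false. It is
#' the ingredient that turns per-alternative power into a single catch-all
#' Type II error (see [mixture_type2_error()] and
#' [integrate_power_over_prior()]). Continuous priors are represented by a
#' quadrature grid on `log(delta)` — the log scale respects the symmetry of a
#' ratio (delta and 1/delta are equally severe violations) — plus an optional
#' point mass exactly at `delta = 1` held outside the mixture.
#'
#' `effect_prior_lognormal()` builds a lognormal prior on delta from its
#' log-scale parameters, discretised by the trapezoid rule. The default
#' (`meanlog = 0`, `sdlog = 0.7`) is centred on the null with ~95% of its mass
#' between a four-fold variance inflation in either direction, a range that
#' spans what applied two-group studies typically treat as a consequential
#' heterogeneity of variance. `effect_prior_discrete()` places probability on
#' a finite set of specific ratios.
#'
#' @param meanlog,sdlog Parameters of the lognormal distribution of delta.
#' @param n_nodes Number of quadrature nodes (odd keeps a node at the median).
#' @param log_range Range of `log(delta)` covered by the grid.
#' @param point_mass_on_null Probability mass placed exactly at `delta = 1`.
#' @return An object of class `effect_prior` with fields `nodes` (increasing
#'   grid on log delta), `weights` (normalised to sum to 1),
#'   `point_mass_on_null`, and the generating `family`/`params` when known.
#' @examples
#' pr <- effect_prior_lognormal(sdlog = 0.7)
#' region_prior_mass(pr, 1/10, 10)
#' @export
effect_prior_lognormal <- function(meanlog = 0, sdlog = 0.7, n_nodes = 81,
                                   log_range = c(-4.6, 4.6),
                                   point_mass_on_null = 0) {
  if (sdlog <= 0) stop_domain("sdlog must be positive")
  if (n_nodes < 3) stop_domain("need at least 3 quadrature nodes")
  check_prob(point_mass_on_null, "point_mass_on_null", open_right = TRUE)
  nodes <- seq(log_range[1], log_range[2], length.out = n_nodes)
  dens <- stats::dnorm(nodes, meanlog, sdlog)  # density of log delta
  h <- diff(nodes)
  trap <- c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
  w <- dens * trap
  new_effect_prior(nodes, w / sum(w), point_mass_on_null,
                   family = "lognormal",
                   params = list(meanlog = meanlog, sdlog = sdlog))
}

#' @rdname effect_prior_lognormal
#' @param delta Positive variance ratios carrying prior mass.
#' @param weights Non-negative weights, one per ratio (normalised internally).
#' @export
effect_prior_discrete <- function(delta, weights = rep(1, length(delta)),
                                  point_mass_on_null = 0) {
  if (length(delta) == 0L) stop_domain("delta must be non-empty")
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop_domain("all delta values must be positive and finite")
  if (length(weights) != length(delta) || any(weights < 0) || sum(weights) <= 0)
    stop_domain("weights must be non-negative with a positive sum")
  if (anyDuplicated(delta)) stop_domain("delta values must be distinct")
  check_prob(point_mass_on_null, "point_mass_on_null", open_right = TRUE)
  ord <- order(delta)
  new_effect_prior(log(delta[ord]), weights[ord] / sum(weights),
                   point_mass_on_null, family = "discrete", params = NULL)
}

new_effect_prior <- function(nodes, weights, point_mass_on_null, family, params) {
  structure(list(nodes = nodes, weights = weights,
                 point_mass_on_null = point_mass_on_null,
                 family = family, params = params),
            class = "effect_prior")
}

#' @export
print.effect_prior <- function(x, ...) {
  cat(sprintf("Effect prior over the variance ratio delta (%s, %d nodes on log delta)\n",
              x$family, length(x$nodes)))
  if (identical(x$family, "lognormal"))
    cat(sprintf("  lognormal(meanlog = %s, sdlog = %s)\n",
                format(x$params$meanlog), format(x$params$sdlog)))
  if (x$point_mass_on_null > 0)
    cat("  point mass at delta = 1:", format(x$point_mass_on_null), "\n")
  invisible(x)
}

#' Prior mass on a region of variance ratios
#'
#' Mass the effect prior assigns to `delta` in `[lower, upper]`, including
#' any point mass at `delta = 1` when the region contains 1. Useful for
#' reading a prior as a statement about an *approximate* null hypothesis,
#' e.g. "the variances do not differ by more than a factor 10".
#'
#' @param prior An `effect_prior`.
#' @param lower,upper Region bounds on the delta scale, `0 < lower < upper`.
#' @return Probability mass in \[0, 1\].
#' @export
region_prior_mass <- function(prior, lower, upper) {
  stopifnot(inherits(prior, "effect_prior"))
  if (!is.finite(lower) && !identical(lower, -Inf)) lower <- as.numeric(lower)
  if (lower <= 0 || upper <= lower)
    stop_domain("need 0 < lower < upper; got [", format(lower), ", ", format(upper), "]")
  inside <- prior$nodes >= log(lower) & prior$nodes <= log(upper)
  pm <- prior$point_mass_on_null
  cont <- sum(prior$weights[inside])
  (1 - pm) * cont + pm * as.numeric(lower <= 1 && 1 <= upper)
}

# Draw n variance ratios from the violation part of an effect prior (the
# point mass at the null, if any, is handled by the caller).
sample_delta <- function(prior, n) {
  stopifnot(inherits(prior, "effect_prior"))
  if (identical(prior$family, "lognormal"))
    stats::rlnorm(n, prior$params$meanlog, prior$params$sdlog)
  else
    exp(prior$nodes[sample.int(length(prior$nodes), n, replace = TRUE,
                               prob = prior$weights)])
}

# Serialization used by the reporting layer's config files.
effect_prior_to_list <- function(prior) {
  if (identical(prior$family, "lognormal"))
    list(family = "lognormal", meanlog = prior$params$meanlog,
         sdlog = prior$params$sdlog,
         point_mass_on_null = prior$point_mass_on_null)
  else
    list(family = "discrete", delta = exp(prior$nodes),
         weights = prior$weights,
         point_mass_on_null = prior$point_mass_on_null)
}

effect_prior_from_list <- function(x) {
  if (is.null(x$family)) stop_usage("effect prior spec needs a 'family' field")
  pm <- if (is.null(x$point_mass_on_null)) 0 else x$point_mass_on_null
  switch(x$family,
    lognormal = effect_prior_lognormal(
      meanlog = if (is.null(x$meanlog)) 0 else x$meanlog,
      sdlog = if (is.null(x$sdlog)) 0.7 else x$sdlog,
      point_mass_on_null = pm),
    discrete = effect_prior_discrete(unlist(x$delta),
      weights = if (is.null(x$weights)) rep(1, length(unlist(x$delta)))
                else unlist(x$weights),
      point_mass_on_null = pm),
    stop_usage("unknown effect prior family: ", x$family))
}
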