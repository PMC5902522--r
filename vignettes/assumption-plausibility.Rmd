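---
title: "Assumption checks, prior plausibility, and what a nonsignificant result buys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assumption checks, prior plausibility, and what a nonsignificant result buys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plausr)
```

## The problem

Before fitting a model, analysts check its assumptions, usually with a
null-hypothesis significance test in which the assumption plays the role of
the null: Levene's test before a pooled *t* test, normality tests before
ANOVA, proportional-hazards checks before Cox regression. When the check is
nonsignificant, practice is to *accept* the assumption and proceed. But a
p-value above α says only that the data are compatible with the assumption —
it does not say the assumption is probable. How probable it is afterwards
depends on two quantities the p-value cannot supply: how plausible the
assumption was beforehand, and how powerful the check was against the
violations worth worrying about.

`plausr` makes both quantities explicit and propagates them. We work
throughout with the equal-variances assumption for two Gaussian groups,
parameterised by the variance ratio δ = σ₁²/σ₂², with H₀: δ = 1; but the
updating layer is generic to any assumption checked at level α with assessed
power 1 − β.

## The updating model

Let p₀ = P(H₀) ∈ (0, 1) be the analyst's prior plausibility. Degenerate
priors are rejected outright — an analyst certain either way has no reason to
test, and the update is vacuous. Let α be the check's size and let β be the
**catch-all Type II error**: the probability of a nonrejection when the
assumption is false, averaged over the specific violations Hᵢ the analyst
considers plausible,

$$\beta \;=\; \frac{\sum_i P(\neg R \mid H_i)\, P(H_i)}{\sum_i P(H_i)}.$$

β is subjective by construction: two analysts with the same data and the same
test but different beliefs about plausible violations assess different β, and
therefore draw different conclusions from the same nonsignificant result.
Bayes' rule gives the posterior plausibility after a nonrejection,

$$P(H_0 \mid \neg R) \;=\;
\frac{p_0 (1-\alpha)}{p_0 (1-\alpha) + (1-p_0)\beta},$$

equivalently: posterior odds = prior odds × (1 − α)/β. Three regimes follow
immediately. If α < 1 − β the check is *informative* and a nonrejection
raises plausibility; if α = 1 − β it carries no information and the posterior
equals the prior; a check with power below its size would anti-confirm.
`operating_characteristics()` classifies these regimes (with a 10⁻¹²
tolerance so that exact boundary cases like α = .05, β = .95 are classified
as neutral despite floating-point noise in 1 − β).

The decision-relevant quantity is the complement 1 − P(H₀ | ¬R): the long-run
proportion of accepted assumptions that are in fact false.
`build_wrong_acceptance_table()` tabulates it:

```{r table}
build_wrong_acceptance_table(priors = c(.01, .10, .20, .50, .80, .90),
                             powers = c(.20, .50, .80, .90, .99), alpha = .05)
```

Cells are rounded half away from zero (base R's round-half-even would print
several cells differently). Reading the table: with power .90 and a prior of
.10, an accepted assumption is wrong 49% of the time; high power alone never
rescues an implausible assumption (short of power exactly 1, where
nonrejection is conclusive — the β = 0 limit, which the package returns as
posterior 1 with an explicit infinite-evidence flag rather than a division by
zero).

When a continuous measure of evidence is available instead of a binary
outcome, `posterior_from_bayes_factor()` applies the same odds algebra with a
Bayes factor for H₀ over its complement: a skeptical prior of .1 combined
with a near-unit Bayes factor of 1.070 yields a posterior of .106 —
skepticism survives a check that the gated workflow would have read as
reassuring.

## Priors over violations and the catch-all power

To get β for the equal-variances check one needs (a) the check's power at
each specific δ and (b) a prior over δ under the catch-all. For the
variance-ratio *F* test the power is exact
(`f_test_variance_power()`): under δ the sample variance ratio is δ times an
F(n₁−1, n₂−1) variate, and we use the equal-tail two-sided acceptance region
(the standard convention; the size is then exactly α at δ = 1). Levene's
statistic has no closed-form power, so `levene_power_mc()` estimates it by
seeded simulation.

Continuous priors are discretised on a fixed trapezoid grid in log δ — the
log scale is the natural one because δ and 1/δ are equally severe violations
— with 81 nodes spanning log δ ∈ [−4.6, 4.6] by default (δ from 1/100 to
100). `integrate_power_over_prior()` then computes the expected power, and
hence β, excluding any point mass at δ = 1 (which belongs to the null, not
the catch-all). The default violation prior is lognormal on δ with median 1
and log-scale 0.7: centred on the null, about 95% of its mass between a
four-fold variance inflation in either direction — the range applied
two-group studies typically treat as consequential heterogeneity. It is a
default to be overridden, not a recommendation; the framework's point is
precisely that this prior is the analyst's to own. The quadrature agrees
with a hierarchical Monte Carlo oracle (draw δ from the prior, simulate
data, run the test) within Monte Carlo error for dispersed, shifted and
heavy-tailed priors; the tests assert this at 10⁵ replicates.

`region_prior_mass()` reads a prior as a statement about an *approximate*
null ("the variances differ by less than a factor 10"), which is often the
hypothesis of real interest: models are robust to small violations, and an
approximate null can be far more plausible a priori than an exact one.

## The tests and a minimal Bayes factor

`levene_test()` (mean-centered by default; `center = "median"` gives the
Brown–Forsythe variant), `student_t()` and `welch_t()` are computed from
their closed-form sufficient statistics, and the unit tests verify them to
10⁻¹⁰ against `car::leveneTest()` and `stats::t.test()`. The in-package
versions exist because the Monte Carlo engine needs them vectorised across
10⁵ replicates, and because matrix-free formulas make the hand-checked
examples in the tests transparent. The mean-centered default follows the
classical form of the statistic.

One honest caveat, measured rather than assumed: Levene's F reference
distribution is asymptotic. At 50 observations per group the mean-centered
test's true size at nominal α = .05 is about .0526, and its p-values fail a
Kolmogorov–Smirnov uniformity check at 10⁴ replicates; by 200 per group the
size is .050 and uniformity holds. The package's size checks therefore run
at n = 200 per group, and simulation summaries at smaller n inherit the
finite-sample size of the real test — which is exactly what an empirical
validation should reflect.

`bf_equal_variances()` supplies a deliberately minimal Bayes factor for
δ = 1 versus the catch-all: the sample variance ratio is sufficient for δ and
distributed as δ·F(n₁−1, n₂−1), so the marginal likelihood under the
catch-all is a one-dimensional integral over the effect prior, evaluated on
its quadrature grid. Working with the ratio eliminates the common scale as a
nuisance parameter (the factor is invariant to rescaling both groups). It is
plumbing for `posterior_from_bayes_factor()` — adequate for two groups and a
ratio prior, and not a replacement for fully specified Bayesian
variance-comparison methods, which handle more groups and richer priors.

## The simulation engine

The Monte Carlo layer validates the analytic claims and measures the
operating characteristics of gated testing. Each scenario
(`scenario_spec()`) draws a truth per replicate — H₀ with probability p₀,
otherwise δ from the effect prior — then generates Gaussian data and applies
the check. This truth-then-data hierarchy is the sampling scheme under which
the wrong-acceptance proportion is a long-run error rate, so it is the only
scheme under which the analytic table can be validated. Group sizes default
to 50 per group, a typical scale for the two-group designs this workflow
appears in; nothing in the machinery depends on that choice, and all
functions take n₁, n₂ explicitly.

Two design choices deserve a note:

* **Randomness.** Each simulation call seeds one vectorised stream with a
  fixed draw order (truths, then violations, then group 1, then group 2),
  restoring the caller's RNG state afterwards. Reproducibility is therefore
  exact and independent of execution order, which is what per-replicate
  substreams would otherwise buy at a large speed cost; derived sub-seeds
  (`plausr:::child_seed`) keep nested simulations — e.g. the power curve
  behind an analytic prediction — independent of the main stream.
* **Power matching.** `validate_table1()` compares simulation against table
  cells indexed by *power*, not by δ, so it inverts the Levene power curve by
  bisection. The curve is built with common random numbers (one standardized
  draw set, rescaled by √δ), making it a deterministic, monotone function of
  δ for a given seed; the bisection runs to bracket collapse because the
  posterior is sensitive to the attained power (near a prior of .10 the
  wrong-acceptance rate moves ≈ 2.5 times any power calibration error). A
  calibration that misses its target by more than .005 raises a classed
  warning, and targets below the check's size are flagged unattainable
  rather than silently mis-matched.

`estimate_gated_type1()` measures the realised Type I error of the two-stage
Levene-then-t procedure under equal means. Under an equal-variance truth the
gated size stays at the nominal level; with unequal variances and the larger
variance in the smaller group, the pooled test is liberal and the Levene gate
only partly protects — the classic argument for using Welch's test
unconditionally rather than gating on a pretest.

## What the synthetic generator does and does not emulate

`generate_two_group()` produces independent Gaussian samples with specified
means and variances — precisely the model under which Student's *t*,
Welch's *t* and the variance-ratio machinery are calibrated, and the model
the motivating workflow assumes. Real response-time-like data are typically
right-skewed, heteroscedastic within group, and serially dependent; none of
that is emulated, deliberately. Passing simulations therefore demonstrate
that the updating arithmetic and the error-rate claims are internally
correct *under the assumed Gaussian model*; they do not certify Levene's
test (whose behaviour under non-normality is a known weakness of
mean-centering) or the t tests on real skewed data.

## Numerical choices, in one place

| Choice | Value | Why |
|---|---|---|
| Table rounding | half away from zero | matches the printed convention for every cell |
| Degenerate prior p₀ ∈ {0,1} | hard error | the update is vacuous; testing is redundant |
| β = 0 after nonrejection | posterior 1 + infinite-evidence flag | well-defined limit, not an overflow |
| Boundary decision p = α | retain H₀ | the retain rule is "p ≥ α" |
| Informativeness classification | tolerance 10⁻¹² on (1−β)−α | float-safe boundary handling |
| Quadrature | 81-node trapezoid on log δ ∈ [−4.6, 4.6] | ratio symmetry; covers δ ∈ [0.01, 100] |
| Two-sided F region | equal tails α/2 | standard convention; size exactly α |
| Levene centering | mean (median via flag) | classical statistic; Brown–Forsythe available |
| Size checks | n = 200 per group, 10⁵ replicates | Levene's F reference has converged there |
| Table validation | n = 50 per group, 20,000 replicates/cell | default design scale; MC error ≪ cell spacing |
| Bisection | bracket collapse, warn above .005 miss | posterior sensitivity to attained power |

## Limitations

The package treats one assumption at a time; joint updating across several
assumptions (normality *and* equal variances) is out of scope, as is any
prior-elicitation protocol — priors are inputs. The Bayes factor is the
minimal ratio-based one described above. Power machinery ships for the two
variance checks only; other assumption tests can reuse the updating layer by
supplying their own α and β.
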