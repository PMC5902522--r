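# Closed-form updating of assumption plausibility.

test_that("decision rule rejects strictly below alpha and retains at the boundary", {
  expect_equal(decide(0.060, 0.05)$outcome, "nonreject")
  expect_equal(decide(0.044, 0.05)$outcome, "reject")
  expect_equal(decide(0.05, 0.05)$outcome, "nonreject")
  expect_error(decide(1.2, 0.05), class = "plausr_domain_error")
  expect_error(decide(0.5, 0), class = "plausr_domain_error")
})

test_that("degenerate priors are rejected: testing a certainty is redundant", {
  expect_error(plausibility_prior(0), class = "plausr_domain_error")
  expect_error(plausibility_prior(1), class = "plausr_domain_error")
  expect_error(posterior_after_nonrejection(1, alpha = .05, beta = .1),
               class = "plausr_domain_error")
  expect_silent(plausibility_prior(1e-12))
})

test_that("posterior after nonrejection matches the closed form", {
  # uninformative test (1 - alpha = beta): posterior equals prior
  expect_equal(posterior_after_nonrejection(.5, alpha = .05, beta = .95)$value, .5)
  # prior .1, alpha .05, beta .1: .095 / .185
  expect_equal(posterior_after_nonrejection(.1, alpha = .05, beta = .10)$value,
               0.095 / 0.185, tolerance = 1e-12)
  # beta = 0: surviving a perfect check proves the assumption
  post <- posterior_after_nonrejection(.3, alpha = .05, beta = 0)
  expect_equal(post$value, 1)
  expect_true(post$infinite_evidence)
})

test_that("posterior after rejection is the Bayes complement pathway", {
  expect_equal(posterior_after_rejection(.5, alpha = .05, beta = .95)$value, .5)
  expect_equal(posterior_after_rejection(.5, alpha = .05, beta = .10)$value,
               0.025 / (0.025 + 0.45), tolerance = 1e-12)
  # monotone in the prior, approaching certainty
  ps <- vapply(c(.5, .9, .99, .9999),
               function(p) posterior_after_rejection(p, alpha = .05, beta = .1)$value,
               numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_gt(ps[4], 0.99)
  expect_error(posterior_after_rejection(.5, alpha = 0, beta = 1),
               class = "plausr_domain_error")
})

test_that("odds update factor is (1 - alpha) / beta with an infinite-evidence signal", {
  expect_equal(odds_update_factor_nonrejection(alpha = .05, beta = .10), 9.5)
  expect_equal(odds_update_factor_nonrejection(alpha = .05, beta = .95), 1.0)
  expect_equal(odds_update_factor_nonrejection(alpha = .05, beta = .01), 95.0)
  expect_warning(f <- odds_update_factor_nonrejection(alpha = .05, beta = 0),
                 class = "plausr_infinite_evidence")
  expect_identical(f, Inf)
})

test_that("a nonsignificant informative check confirms; an uninformative one does not", {
  # dense grid including exact alpha = 1 - beta cases
  grid <- expand.grid(p0 = seq(.02, .98, by = .04),
                      alpha = seq(.02, .98, by = .04),
                      beta = seq(.02, .98, by = .04))
  post <- with(grid, p0 * (1 - alpha) / (p0 * (1 - alpha) + (1 - p0) * beta))
  gap <- with(grid, (1 - alpha) - beta)  # informativeness margin, float-safe
  neutral <- abs(gap) < 1e-9
  expect_true(all(post[gap > 1e-9] > grid$p0[gap > 1e-9]))
  expect_true(any(neutral))  # the grid really exercises the equality case
  expect_equal(post[neutral], grid$p0[neutral], tolerance = 1e-12)
  expect_true(all(post[gap < -1e-9] < grid$p0[gap < -1e-9]))
})

test_that("odds form and probability form of the update are mutually consistent", {
  grid <- expand.grid(p0 = seq(.05, .95, by = .05),
                      alpha = seq(.01, .2, by = .01),
                      beta = seq(.05, .95, by = .05))
  direct <- mapply(function(p, a, b)
    posterior_after_nonrejection(p, alpha = a, beta = b)$value,
    grid$p0, grid$alpha, grid$beta)
  odds <- grid$p0 / (1 - grid$p0) * (1 - grid$alpha) / grid$beta
  expect_equal(direct, odds / (1 + odds), tolerance = 1e-12)
})

test_that("posterior for H0 and for its complement sum to one", {
  for (p0 in c(.1, .5, .9)) for (b in c(.1, .5, .9)) {
    ph0 <- posterior_after_nonrejection(p0, alpha = .05, beta = b)$value
    # identical computation with the hypotheses relabelled: the complement's
    # "nonrejection survival" rates swap roles
    pnot <- (1 - p0) * b / ((1 - p0) * b + p0 * (1 - .05))
    expect_equal(ph0 + pnot, 1, tolerance = 1e-15)
  }
})

test_that("posterior rises with the prior and falls with the miss rate", {
  p0s <- seq(.05, .95, by = .05)
  post_in_p0 <- vapply(p0s, function(p)
    posterior_after_nonrejection(p, alpha = .05, beta = .2)$value, numeric(1))
  expect_true(all(diff(post_in_p0) > 0))
  betas <- seq(.05, .95, by = .05)
  post_in_beta <- vapply(betas, function(b)
    posterior_after_nonrejection(.3, alpha = .05, beta = b)$value, numeric(1))
  expect_true(all(diff(post_in_beta) < 0))
})

test_that("wrong-acceptance proportion is the posterior complement", {
  expect_equal(wrong_acceptance_proportion(.10, .05, .90),
               1 - 0.095 / 0.185, tolerance = 1e-12)
  expect_equal(wrong_acceptance_proportion(.5, .05, .05), .5)  # power = alpha
  expect_equal(wrong_acceptance_proportion(.1, .05, 1), 0)    # perfect power
})

test_that("wrong-acceptance table reproduces the canonical 6 x 5 grid", {
  printed <- rbind(c(.99, .98, .95, .91, .51),
                   c(.88, .83, .65, .49, .09),
                   c(.77, .68, .46, .30, .04),
                   c(.46, .34, .17, .10, .01),
                   c(.17, .12, .05, .03, .00),
                   c(.09, .06, .02, .01, .00))
  tab <- build_wrong_acceptance_table(c(.01, .10, .20, .50, .80, .90),
                                      c(.20, .50, .80, .90, .99),
                                      alpha = .05, decimals = 2)
  expect_equal(unname(tab$cells), printed)
  # cells shrink as the prior grows, for every informative column
  expect_true(all(apply(tab$cells, 2, function(col) all(diff(col) <= 0))))
  # single-cell edge cases
  expect_equal(unname(build_wrong_acceptance_table(.5, .05, .05)$cells[1, 1]), .50)
  expect_equal(unname(build_wrong_acceptance_table(.1, 1, .05)$cells[1, 1]), .00)
  expect_error(build_wrong_acceptance_table(numeric(0), .5),
               class = "plausr_domain_error")
})

test_that("unrounded table cells round back to the 2-decimal table", {
  fine <- build_wrong_acceptance_table(c(.01, .5, .9), c(.2, .9), decimals = 4)
  coarse <- build_wrong_acceptance_table(c(.01, .5, .9), c(.2, .9), decimals = 2)
  expect_equal(plausr:::round_half_up(fine$cells, 2), coarse$cells,
               ignore_attr = TRUE)
})

test_that("Bayes factor updating multiplies prior odds and chains coherently", {
  expect_equal(plausr:::round_half_up(posterior_from_bayes_factor(.1, 1.070)$value, 3),
               .106)
  expect_equal(posterior_from_bayes_factor(.37, 1)$value, .37, tolerance = 1e-15)
  expect_equal(posterior_from_bayes_factor(.5, 3)$value, .75, tolerance = 1e-12)
  # sequential coherence: updating twice equals one update by the product
  for (p in c(.1, .6)) for (b1 in c(.4, 2.5)) for (b2 in c(.9, 7)) {
    step <- posterior_from_bayes_factor(
      posterior_from_bayes_factor(p, b1)$value, b2)$value
    expect_equal(step, posterior_from_bayes_factor(p, b1 * b2)$value,
                 tolerance = 1e-12)
  }
  expect_error(posterior_from_bayes_factor(.5, 0), class = "plausr_domain_error")
  expect_error(posterior_from_bayes_factor(.5, -2), class = "plausr_domain_error")
})

test_that("operating characteristics flag informativeness as alpha < 1 - beta", {
  expect_true(operating_characteristics(.05, .1)$informative)
  expect_false(operating_characteristics(.05, .95)$informative)
  expect_false(operating_characteristics(.2, .9)$informative)
  expect_error(operating_characteristics(1, .5), class = "plausr_domain_error")
  expect_error(operating_characteristics(.05, 1.1), class = "plausr_domain_error")
})
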