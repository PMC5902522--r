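# The two-group frequentist tests and the minimal variance Bayes factor.

test_that("Levene statistic matches hand-computed ANOVA on absolute deviations", {
  # identical deviation patterns: no between-group spread at all
  r <- levene_test(two_group_sample(c(1, 3), c(5, 7)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # |z| = (1,0,1) vs (2,0,2): SSB = 2/3, SSW = 10/3, F = (2/3)/(10/12) = 0.8
  r <- levene_test(two_group_sample(c(1, 2, 3), c(2, 4, 6)), center = "mean")
  expect_equal(r$statistic, 0.8, tolerance = 1e-12)
  expect_equal(c(r$df1, r$df2), c(1, 4))
  expect_equal(r$p_value, pf(0.8, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("Levene is location invariant and tracks scale changes", {
  s <- two_group_sample(c(1.2, 3.4, 2.2, 5.1), c(0.4, 6.1, 2.0, 3.3))
  base <- levene_test(s)
  shifted <- levene_test(two_group_sample(s$group1 + 100, s$group2 - 3))
  expect_equal(shifted$statistic, base$statistic, tolerance = 1e-9)
  scaled <- levene_test(two_group_sample(s$group1 * 10, s$group2))
  expect_false(isTRUE(all.equal(scaled$statistic, base$statistic)))
  expect_error(levene_test(two_group_sample(c(2, 2, 2), c(5, 5, 5))),
               class = "plausr_data_error")
})

test_that("Levene agrees with the car implementation for both centerings", {
  skip_if_not_installed("car")
  set.seed(99)
  for (i in 1:5) {
    g1 <- rnorm(13, sd = runif(1, .5, 3)); g2 <- rnorm(21, sd = runif(1, .5, 3))
    dat <- data.frame(y = c(g1, g2), g = factor(rep(1:2, c(13, 21))))
    for (ctr in c("mean", "median")) {
      ours <- levene_test(two_group_sample(g1, g2), center = ctr)
      ref <- car::leveneTest(y ~ g, data = dat, center = get(ctr))
      expect_equal(ours$statistic, ref$`F value`[1], tolerance = 1e-10)
      expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
    }
  }
})

test_that("Student t matches the hand computation and stats::t.test", {
  r <- student_t(two_group_sample(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df2, 4)
  set.seed(7)
  g1 <- rnorm(9, 1, 2); g2 <- rnorm(17, 0, 2)
  ours <- student_t(two_group_sample(g1, g2))
  ref <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # swapping groups flips the sign, not the p-value
  swap <- student_t(two_group_sample(g2, g1))
  expect_equal(swap$statistic, -ours$statistic, tolerance = 1e-12)
  expect_equal(swap$p_value, ours$p_value, tolerance = 1e-12)
  same <- two_group_sample(g1, g1)
  expect_equal(student_t(same)$statistic, 0)
  expect_equal(student_t(same)$p_value, 1)
})

test_that("Welch t matches stats::t.test and collapses to Student when balanced", {
  set.seed(8)
  g1 <- rnorm(11, 0, 1); g2 <- rnorm(23, 0, 4)
  ours <- welch_t(two_group_sample(g1, g2))
  ref <- t.test(g1, g2)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df2, unname(ref$parameter), tolerance = 1e-8)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # equal sizes and equal sample variances: identical statistic and df
  g3 <- rnorm(12); g4 <- (g3 - mean(g3)) + 5  # exactly equal sample variance
  w <- welch_t(two_group_sample(g3, g4)); s <- student_t(two_group_sample(g3, g4))
  expect_equal(w$statistic, s$statistic, tolerance = 1e-12)
  expect_equal(w$df2, s$df2, tolerance = 1e-9)
  expect_equal(w$p_value, s$p_value, tolerance = 1e-10)
  # the 1-2-3 vs 4-5-6 case has equal variances by construction
  expect_equal(welch_t(two_group_sample(1:3, 4:6))$statistic, -3 / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_error(welch_t(two_group_sample(c(1, 1, 1), c(2, 3, 4))),
               class = "plausr_data_error")
})

test_that("exact test p-values are uniform under their null", {
  set.seed(1234)
  B <- 1e4; n1 <- 15; n2 <- 12
  x1 <- matrix(rnorm(n1 * B), n1); x2 <- matrix(rnorm(n2 * B), n2)
  crit <- 1.6276 / sqrt(B)  # 1% Kolmogorov-Smirnov critical value
  for (fn in c("student_p_matrix", "welch_p_matrix")) {
    p <- getFromNamespace(fn, "plausr")(x1, x2)
    d <- suppressWarnings(ks.test(p, "punif")$statistic)
    expect_lt(unname(d), crit)
  }
  # Levene's F reference is asymptotic: uniformity holds at large n
  set.seed(4321)
  n <- 200
  x1 <- matrix(rnorm(n * B), n); x2 <- matrix(rnorm(n * B), n)
  d <- suppressWarnings(ks.test(plausr:::levene_p_matrix(x1, x2), "punif")$statistic)
  expect_lt(unname(d), crit)
})

test_that("the variance Bayes factor favours H0 for equal spreads and is scale free", {
  s <- generate_two_group(200, 200, var1 = 1, var2 = 1, seed = 41)
  pr <- effect_prior_lognormal(sdlog = 0.7)
  bf <- bf_equal_variances(s, pr)
  expect_gt(bf, 1)
  # fine-grid oracle: 10x node density changes the answer only marginally
  fine <- effect_prior_lognormal(sdlog = 0.7, n_nodes = 801)
  expect_equal(bf, bf_equal_variances(s, fine), tolerance = 1e-3)
  # rescaling both groups leaves the factor unchanged
  s2 <- two_group_sample(s$group1 * 37.5, s$group2 * 37.5)
  expect_equal(bf_equal_variances(s2, pr), bf, tolerance = 1e-12)
  # swapping groups under a log-symmetric prior leaves it unchanged
  swap <- two_group_sample(s$group2, s$group1)
  expect_equal(bf_equal_variances(swap, pr), bf, tolerance = 1e-6)
  # feeding any BF of 1 into the updater returns the prior
  expect_equal(posterior_from_bayes_factor(.2, 1)$value, .2)
})

test_that("two-group files round-trip and malformed files fail loudly", {
  path <- write_two_group_csv(10, 12, delta = 1, seed = 3)
  s <- read_two_group(path)
  expect_s3_class(s, "two_group_sample")
  expect_equal(length(s$group1), 10)
  expect_equal(length(s$group2), 12)
  expect_equal(s$labels, c("a", "b"))
  expect_error(read_two_group(path, group_col = "sex"), class = "plausr_data_error")
  expect_error(read_two_group(file.path(tempdir(), "absent.csv")),
               class = "plausr_data_error")
  three <- data.frame(value = rnorm(9), group = rep(c("a", "b", "c"), 3))
  p3 <- tempfile(fileext = ".csv"); write.csv(three, p3, row.names = FALSE)
  expect_error(read_two_group(p3), class = "plausr_data_error")
  # TSV by extension
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(value = rnorm(6), group = rep(c("x", "y"), 3)),
              tsv, sep = "\t", row.names = FALSE)
  expect_s3_class(read_two_group(tsv), "two_group_sample")
})
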