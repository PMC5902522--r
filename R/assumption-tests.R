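#' Two-group sample container
#'
#' Holds the two numeric vectors an assumption check runs on. Both groups
#' need at least two finite observations.
#'
#' @param group1,group2 Numeric vectors of observations.
#' @param labels Character vector of length 2 naming the groups.
#' @return An object of class `two_group_sample`.
#' @export
two_group_sample <- function(group1, group2, labels = c("group1", "group2")) {
  group1 <- as.numeric(group1); group2 <- as.numeric(group2)
  if (length(group1) < 2L || length(group2) < 2L)
    stop_data("each group needs at least 2 observations")
  if (any(!is.finite(group1)) || any(!is.finite(group2)))
    stop_data("all observations must be finite")
  if (length(labels) != 2L) stop_data("labels must have length 2")
  structure(list(group1 = group1, group2 = group2,
                 labels = as.character(labels)),
            class = "two_group_sample")
}

#' @export
print.two_group_sample <- function(x, ...) {
  cat(sprintf("Two-group sample: %s (n = %d, var = %.4g), %s (n = %d, var = %.4g)\n",
              x$labels[1], length(x$group1), stats::var(x$group1),
              x$labels[2], length(x$group2), stats::var(x$group2)))
  invisible(x)
}

#' Read a two-group sample from a delimited file
#'
#' Reads a CSV or TSV file with one numeric value column and one group
#' column holding exactly two distinct labels.
#'
#' @param path Path to the file. Files ending in `.tsv`/`.txt` are read as
#'   tab-separated, otherwise comma-separated; `sep` overrides.
#' @param value_col,group_col Column names.
#' @param sep Field separator, or `NULL` to infer from the extension.
#' @return A [two_group_sample()], groups ordered by first appearance.
#' @export
read_two_group <- function(path, value_col = "value", group_col = "group",
                           sep = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c(value_col, group_col))
    if (!col %in% names(df))
      stop_data("column '", col, "' not found in ", path,
                " (columns: ", paste(names(df), collapse = ", "), ")")
  vals <- df[[value_col]]
  if (!is.numeric(vals)) stop_data("value column '", value_col, "' is not numeric")
  groups <- as.character(df[[group_col]])
  labs <- unique(groups)
  if (length(labs) != 2L)
    stop_data("group column '", group_col, "' must contain exactly 2 distinct ",
              "labels, found ", length(labs))
  two_group_sample(vals[groups == labs[1]], vals[groups == labs[2]], labs)
}

new_test_result <- function(statistic, df1, df2, p_value, test_name) {
  structure(list(statistic = statistic, df1 = df1, df2 = df2,
                 p_value = p_value, test_name = test_name),
            class = "plausr_test_result")
}

#' @export
print.plausr_test_result <- function(x, ...) {
  df <- if (is.na(x$df1)) sprintf("df = %.4g", x$df2)
        else sprintf("df = (%g, %.4g)", x$df1, x$df2)
  cat(sprintf("%s: statistic = %.4f, %s, p = %.4g\n",
              x$test_name, x$statistic, df, x$p_value))
  invisible(x)
}

#' Levene's test for equality of two variances
#'
#' One-way ANOVA F test on the absolute deviations of each observation from
#' its group center: classical Levene uses the group mean, the
#' Brown–Forsythe variant the group median. The statistic is referred to an
#' F(1, n1 + n2 - 2) distribution; that reference is asymptotic, and at
#' moderate group sizes the mean-centered test is slightly liberal (see the
#' package vignette).
#'
#' @param sample A [two_group_sample()].
#' @param center `"mean"` (default, classical Levene) or `"median"`.
#' @return A `plausr_test_result` with the F statistic, its degrees of
#'   freedom and the upper-tail p-value.
#' @examples
#' levene_test(two_group_sample(c(1, 2, 3), c(2, 4, 6)))
#' @export
levene_test <- function(sample, center = c("mean", "median")) {
  stopifnot(inherits(sample, "two_group_sample"))
  center <- match.arg(center)
  cfun <- if (center == "mean") mean else stats::median
  z1 <- abs(sample$group1 - cfun(sample$group1))
  z2 <- abs(sample$group2 - cfun(sample$group2))
  n1 <- length(z1); n2 <- length(z2); N <- n1 + n2
  m1 <- mean(z1); m2 <- mean(z2); g <- (n1 * m1 + n2 * m2) / N
  ssb <- n1 * (m1 - g)^2 + n2 * (m2 - g)^2
  ssw <- sum((z1 - m1)^2) + sum((z2 - m2)^2)
  if (all(z1 == 0) && all(z2 == 0))
    stop_data("degenerate data: no spread in either group")
  # identical deviation profiles give SSB = 0 (F = 0, p = 1) even when the
  # within-group SS also vanishes
  f <- if (ssb == 0) 0 else if (ssw == 0) Inf else (ssb / 1) / (ssw / (N - 2))
  new_test_result(f, 1, N - 2, stats::pf(f, 1, N - 2, lower.tail = FALSE),
                  paste0("Levene (", center, "-centered)"))
}

#' Student's pooled-variance t test for two independent groups
#'
#' @param sample A [two_group_sample()].
#' @return A `plausr_test_result` with the t statistic (group1 minus group2),
#'   `df2 = n1 + n2 - 2`, and the two-sided p-value.
#' @export
student_t <- function(sample) {
  stopifnot(inherits(sample, "two_group_sample"))
  x <- sample$group1; y <- sample$group2
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop_data("degenerate data: pooled variance is zero")
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  new_test_result(tt, NA_real_, df,
                  2 * stats::pt(abs(tt), df, lower.tail = FALSE), "Student t")
}

#' Welch's unequal-variances t test for two independent groups
#'
#' Uses the Welch–Satterthwaite approximation for the (generally fractional)
#' degrees of freedom; with equal group sizes and equal sample variances it
#' coincides with Student's test.
#'
#' @param sample A [two_group_sample()].
#' @return A `plausr_test_result` with the t statistic, fractional `df2`,
#'   and the two-sided p-value.
#' @export
welch_t <- function(sample) {
  stopifnot(inherits(sample, "two_group_sample"))
  x <- sample$group1; y <- sample$group2
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 || v2 == 0) stop_data("degenerate data: a group has zero variance")
  se2 <- v1 / n1 + v2 / n2
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  new_test_result(tt, NA_real_, df,
                  2 * stats::pt(abs(tt), df, lower.tail = FALSE), "Welch t")
}

#' A minimal Bayes factor for equality of two variances
#'
#' Computes BF(H0 : delta = 1 versus the catch-all) from the sample variance
#' ratio, whose sampling distribution under a true ratio `delta` is `delta`
#' times an F(n1 - 1, n2 - 1) variate. The marginal likelihood under the
#' catch-all integrates that density over the effect prior's quadrature grid.
#' Working with the variance ratio removes the common scale as a nuisance
#' parameter, so the factor is invariant to rescaling both groups. This is a
#' deliberately simple sufficient-statistic Bayes factor intended as
#' plumbing for [posterior_from_bayes_factor()]; it is not a substitute for
#' fully specified Bayesian variance-comparison methods.
#'
#' @param sample A [two_group_sample()].
#' @param prior An `effect_prior` over the variance ratio under the catch-all.
#' @return The Bayes factor for H0 over the catch-all (`> 1` favours equal
#'   variances).
#' @export
bf_equal_variances <- function(sample, prior = effect_prior_lognormal()) {
  stopifnot(inherits(sample, "two_group_sample"), inherits(prior, "effect_prior"))
  v1 <- stats::var(sample$group1); v2 <- stats::var(sample$group2)
  if (v1 == 0 || v2 == 0) stop_data("degenerate data: a group has zero variance")
  d1 <- length(sample$group1) - 1; d2 <- length(sample$group2) - 1
  fobs <- v1 / v2
  # density of the observed ratio when the true ratio is delta
  lik <- function(delta) stats::df(fobs / delta, d1, d2) / delta
  m0 <- lik(1)
  m1 <- sum(lik(exp(prior$nodes)) * prior$weights)
  bf <- m0 / m1
  if (!is.finite(bf))
    stop_domain("non-finite Bayes factor (m0 = ", format(m0), ", m1 = ",
                format(m1), "); the prior grid may not cover the observed ratio ",
                format(fobs))
  bf
}

# ---- vectorized internals used by the Monte Carlo engine ------------------
# Each takes matrices with one replicate per column and returns a p-value per
# column. These mirror levene_test() / student_t() / welch_t() exactly.

levene_p_matrix <- function(x1, x2, center = "mean") {
  cfun <- if (center == "mean") colMeans else function(m) apply(m, 2, stats::median)
  z1 <- abs(sweep(x1, 2, cfun(x1))); z2 <- abs(sweep(x2, 2, cfun(x2)))
  n1 <- nrow(x1); n2 <- nrow(x2); N <- n1 + n2
  m1 <- colMeans(z1); m2 <- colMeans(z2); g <- (n1 * m1 + n2 * m2) / N
  ssb <- n1 * (m1 - g)^2 + n2 * (m2 - g)^2
  ssw <- colSums(sweep(z1, 2, m1)^2) + colSums(sweep(z2, 2, m2)^2)
  stats::pf(ssb / (ssw / (N - 2)), 1, N - 2, lower.tail = FALSE)
}

student_p_matrix <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  v1 <- colSums(sweep(x1, 2, colMeans(x1))^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, colMeans(x2))^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (colMeans(x1) - colMeans(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE)
}

welch_p_matrix <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  v1 <- colSums(sweep(x1, 2, colMeans(x1))^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, colMeans(x2))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (colMeans(x1) - colMeans(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(abs(tt), df, lower.tail = FALSE)
}
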