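test_that("partial correlation matches the brute-force residualization oracle", {
  set.seed(101)
  n <- 80
  z <- cbind(age = rnorm(n, 25, 8), bsa = rnorm(n, 1.5, 0.2))
  x <- 0.4 * z[, 1] + rnorm(n)
  y <- -0.2 * z[, 1] + 0.5 * z[, 2] + rnorm(n)
  pc <- partialCorrelation(x, y, z)
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  expect_equal(pc$estimate, stats::cor(rx, ry), tolerance = 1e-10)
  expect_equal(pc$df, n - 2 - 2)
  ## p-value agrees with the t transform of r
  tref <- pc$estimate * sqrt(pc$df) / sqrt(1 - pc$estimate^2)
  expect_equal(pc$p.value, 2 * stats::pt(-abs(tref), pc$df), tolerance = 1e-12)
})

test_that("with no adjusters the partial correlation is plain Pearson", {
  set.seed(7)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partialCorrelation(x, y)$estimate, stats::cor(x, y),
               tolerance = 1e-12)
  expect_error(partialCorrelation(x, rep(1, 30)), "degenerate variable")
})

test_that("adjusting removes a planted confounder", {
  set.seed(11)
  n <- 500
  z <- rnorm(n)
  x <- 1 + 2 * z + rnorm(n)
  y <- -0.5 + 1.5 * z + rnorm(n)
  expect_gt(abs(stats::cor(x, y)), 0.5)
  expect_lt(abs(partialCorrelation(x, y, cbind(z = z))$estimate), 0.1)
})

test_that("missing values are excluded pairwise, never treated as zero", {
  set.seed(3)
  x <- rnorm(40); y <- x + rnorm(40); z <- rnorm(40)
  x[c(4, 9)] <- NA; z[17] <- NA
  pc <- partialCorrelation(x, y, cbind(z = z))
  expect_equal(pc$nUsed, 37)
  keep <- is.finite(x) & is.finite(z)
  expect_equal(pc$estimate,
               partialCorrelation(x[keep], y[keep],
                                  cbind(z = z[keep]))$estimate)
})

test_that("leverage follows the hat-matrix rule with threshold 3(k+1)/n", {
  set.seed(19)
  n <- 50
  ## balanced design: bounded covariates, no leverage outliers
  z <- seq(-1.5, 1.5, length.out = n)
  x <- runif(n, -1, 1)
  y <- x + rnorm(n)
  lv <- leveragePoints(x, y, cbind(z = z))
  expect_equal(mean(lv$leverage), 3 / n, tolerance = 1e-12)  # (k+1)/n
  expect_equal(lv$threshold, 3 * 3 / n, tolerance = 1e-12)
  ## balanced design: nothing excluded
  expect_length(lv$excluded, 0)
  ## one covariate point at 10 SD is excluded
  z2 <- z; z2[25] <- 10
  lv2 <- leveragePoints(x, y, cbind(z = z2))
  expect_true(25 %in% lv2$excluded)
  ## hat values agree with lm's diagnostics
  fit <- stats::lm(y ~ z2 + x)
  expect_equal(lv2$leverage, unname(stats::hatvalues(fit)),
               tolerance = 1e-10)
  expect_error(leveragePoints(x, y, cbind(a = z, b = z)), "collinear design")
})

test_that("partial correlation can drop leverage points before correlating", {
  set.seed(23)
  n <- 40
  z <- rnorm(n); z[n] <- 12
  x <- rnorm(n); y <- rnorm(n)
  pc <- partialCorrelation(x, y, cbind(age = z), excludeLeverage = TRUE,
                           ids = sprintf("P%02d", 1:n))
  expect_true("P40" %in% pc$excluded)
  expect_equal(pc$nUsed, n - length(pc$excluded))
})

test_that("group comparison reduces to the textbook pooled t statistic", {
  a <- c(5.1, 4.8, 5.5, 5.0, 4.7)
  b <- c(6.0, 6.3, 5.9, 6.5, 6.1, 6.2)
  gc <- compareGroups(c(a, b), rep(c("A", "B"), c(5, 6)))
  sp2 <- ((4 * stats::var(a) + 5 * stats::var(b)) / 9)
  tref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 6))
  expect_equal(gc$statistic, tref, tolerance = 1e-12)
  expect_equal(gc$p.value, 2 * stats::pt(-abs(tref), 9), tolerance = 1e-12)
  ## identical groups: t = 0, p = 1
  gc0 <- compareGroups(rep(c(1, 2, 3), 2), rep(c("A", "B"), each = 3))
  expect_equal(gc0$statistic, 0)
  expect_equal(gc0$p.value, 1)
  ## power sanity on well-separated samples
  set.seed(5)
  v <- c(rnorm(1000), rnorm(1000, 1))
  gcP <- compareGroups(v, rep(c("a", "b"), each = 1000))
  expect_lt(gcP$p.value, 1e-10)
  expect_error(compareGroups(c(1, 2, 3), c("A", "A", "B")), "empty group")
})

test_that("Fisher z-test matches its direct formula and is antisymmetric", {
  cz <- compareCorrelations(0.8, 50, 0.0, 50)
  zref <- (atanh(0.8) - atanh(0)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(cz$statistic, zref, tolerance = 1e-12)
  expect_lt(cz$p.value, 0.01)
  expect_equal(compareCorrelations(0.4, 30, 0.4, 60)$statistic, 0)
  expect_equal(compareCorrelations(0.4, 30, 0.4, 60)$p.value, 1)
  sw <- compareCorrelations(0.0, 50, 0.8, 50)
  expect_equal(sw$statistic, -cz$statistic)
  expect_error(compareCorrelations(1, 10, 0.5, 10), "transform undefined")
  expect_error(compareCorrelations(0.5, 3, 0.5, 10), ">= 4")
})

test_that("summaries format as mean +- SD or median (IQR)", {
  s <- summarizeVariable(c(1, 2, 3, 4, 5), "median_iqr")
  expect_equal(s$median, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  expect_match(s$formatted, "3 \\(2, 4\\)")
  cst <- summarizeVariable(rep(2.5, 4), "mean_sd")
  expect_equal(cst$mean, 2.5)
  expect_equal(cst$sd, 0)
  one <- summarizeVariable(7, "mean_sd")
  expect_true(one$sdUndefined)
  expect_error(summarizeVariable(c(NA_real_, NA_real_)), "no data")
})

test_that("a cohort analysis plan produces a tidy results table", {
  d <- syntheticCohort(n = 40, seed = 77)
  d$hf <- rep(c(TRUE, FALSE), 20)
  plan <- list(
    list(name = "elke_vo2", type = "correlation", x = "elKeIndex",
         y = "vo2Peak", adjusters = "age", excludeLeverage = TRUE),
    list(name = "vo2_by_hf", type = "group", value = "vo2Peak",
         group = "hf"),
    list(name = "age", type = "summary", value = "age",
         style = "median_iqr"))
  res <- cohortAnalysis(d, plan)
  expect_equal(nrow(res), 3)
  expect_equal(res$analysis, c("elke_vo2", "vo2_by_hf", "age"))
  expect_true(all(is.finite(res$p.value[1:2])))
  expect_error(cohortAnalysis(d, list(list(type = "correlation", x = "nope",
                                           y = "vo2Peak"))),
               "not in table")
})
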