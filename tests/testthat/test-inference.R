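test_that("2x2 cross-tabulation matches the published stage-by-outcome counts", {
  # stage IV exposure: dead = 28 III + 16 IV, live = 1 II + 21 III + 6 IV
  stage <- c(rep(3, 28), rep(4, 16), rep(2, 1), rep(3, 21), rep(4, 6))
  death <- rep(c(TRUE, FALSE), c(44, 28))
  tab <- contingency_2x2(stage == 4, death)
  expect_equal(tab$tp, 16)
  expect_equal(tab$fp, 6)
  expect_equal(tab$fn, 28)
  expect_equal(tab$tn, 22)
})

test_that("2x2 symmetry and missing-data contracts hold", {
  x <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  y <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  tab <- contingency_2x2(x, x)
  expect_equal(tab$fp, 0)
  expect_equal(tab$fn, 0)
  t1 <- contingency_2x2(x, y)
  t2 <- contingency_2x2(!x, y)
  expect_equal(t1$tp, t2$fn)
  expect_equal(t1$fp, t2$tn)
  xm <- c(TRUE, NA, FALSE)
  ym <- c(TRUE, TRUE, NA)
  tab <- contingency_2x2(xm, ym)
  expect_equal(tab$tp + tab$fp + tab$fn + tab$tn, 1)
  expect_error(contingency_2x2(c(NA, NA), c(TRUE, FALSE)), "empty 2x2")
})

test_that("odds ratios with Wald intervals reproduce published rows", {
  # post-NACT lymphocyte count: OR 10.00 (2.81-35.50)
  or1 <- odds_ratio_wald(table2x2(40, 14, 4, 14))
  expect_equal(truncate2(or1$or_point), 10.00)
  expect_equal(truncate2(or1$ci_low), 2.81)
  expect_equal(truncate2(or1$ci_high), 35.50)
  expect_lt(or1$p, 0.001)
  # pre-treatment lymphocyte count: OR 8.05 (2.08-31.05), p 0.002
  or2 <- odds_ratio_wald(table2x2(23, 3, 20, 21))
  expect_equal(truncate2(or2$or_point), 8.05)
  expect_equal(truncate2(or2$ci_low), 2.08)
  expect_equal(truncate2(or2$ci_high), 31.05)
  expect_equal(round(or2$p, 3), 0.002)
  # uniform table
  expect_equal(odds_ratio_wald(table2x2(1, 1, 1, 1))$or_point, 1)
})

test_that("odds ratio invariances and zero-cell handling", {
  tab <- table2x2(12, 5, 7, 20)
  a <- odds_ratio_wald(tab)
  b <- odds_ratio_wald(table2x2(tab$tn, tab$fn, tab$fp, tab$tp))
  expect_equal(a$or_point, b$or_point, tolerance = 1e-12)
  expect_equal(a$ci_low, b$ci_low, tolerance = 1e-12)
  expect_true(a$ci_low <= a$or_point && a$or_point <= a$ci_high)
  # scaling all cells by k shrinks the CI around the same point
  k <- 4
  big <- odds_ratio_wald(table2x2(12 * k, 5 * k, 7 * k, 20 * k))
  expect_equal(big$or_point, a$or_point, tolerance = 1e-12)
  expect_lt(log(big$ci_high / big$ci_low), log(a$ci_high / a$ci_low))
  # Haldane-Anscombe correction on a zero cell
  z <- odds_ratio_wald(table2x2(10, 0, 5, 8))
  expect_true(z$corrected)
  expect_true(is.finite(z$or_point))
  expect_false(a$corrected)
  expect_error(odds_ratio_wald(table2x2(0, 3, 4, 0)), "diagonal")
})

test_that("exp(logistic slope) equals the cross-product odds ratio", {
  counts <- table2x2(40, 14, 4, 14)
  x <- c(rep(1, 54), rep(0, 18))
  y <- c(rep(TRUE, 40), rep(FALSE, 14), rep(TRUE, 4), rep(FALSE, 14))
  fit <- logistic_fit(cbind(intercept = 1, exposed = x), y)
  expect_equal(unname(exp(fit$coefficients[2])),
               odds_ratio_wald(counts)$or_point, tolerance = 1e-6)
  expect_equal(unname(fit$or$ci_low[2]), odds_ratio_wald(counts)$ci_low,
               tolerance = 1e-6)
  expect_equal(unname(fit$or$ci_high[2]), odds_ratio_wald(counts)$ci_high,
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("logistic fit matches glm on a two-predictor problem", {
  set.seed(301)
  n <- 300
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.4)
  y <- runif(n) < plogis(-0.5 + 0.8 * x1 - 0.6 * x2)
  fit <- logistic_fit(cbind(1, x1, x2), y)
  ref <- stats::glm(y ~ x1 + x2, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
})

test_that("logistic fit detects degenerate problems", {
  expect_error(logistic_fit(cbind(1, rnorm(10)), rep(TRUE, 10)), "constant")
  x <- c(rep(0, 20), rep(1, 20))
  y <- x == 1
  expect_error(suppressWarnings(logistic_fit(cbind(1, x), y)), "separation")
})

test_that("a null slope is recovered as near zero on a large sample", {
  set.seed(302)
  n <- 10000
  x <- rbinom(n, 1, 0.5)
  y <- runif(n) < 0.4
  fit <- logistic_fit(cbind(1, x), y)
  expect_lt(abs(fit$coefficients[2]), 0.15)
  ci <- fit$coefficients[2] + c(-1.96, 1.96) * fit$se[2]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("group comparison routes between Student t and Mann-Whitney", {
  set.seed(303)
  x <- rnorm(30)
  res <- compare_groups(x, x)
  expect_equal(res$p, 1)

  a <- rnorm(30)
  b <- rnorm(30, 3)
  res <- compare_groups(a, b)
  expect_equal(res$test_used, "t")
  expect_lt(res$p, 0.001)

  h1 <- rcauchy(50)
  h2 <- rcauchy(50)
  res <- compare_groups(h1, h2)
  expect_equal(res$test_used, "mann_whitney")

  expect_warning(res <- compare_groups(c(1, 2), rnorm(10)), "size < 3")
  expect_equal(res$test_used, "mann_whitney")
})

test_that("Mann-Whitney path agrees with wilcox.test", {
  set.seed(304)
  a <- rcauchy(25)
  b <- rcauchy(25, 1)
  res <- compare_groups(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("rank correlation handles sign, ties, nulls and degenerate input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(rank_correlation(x, x)$rho, 1)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  set.seed(305)
  ps <- replicate(200, rank_correlation(rnorm(50), rnorm(50))$p)
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(rank_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_error(rank_correlation(1:3, 3:1), ">= 4")
})
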