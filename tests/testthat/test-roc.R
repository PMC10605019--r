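test_that("ROC points match exhaustive counting on random tied data", {
  set.seed(101)
  for (rep in 1:25) {
    inst <- random_roc_instance(20)
    roc <- build_roc(inst$values, inst$labels, "high_abnormal")
    for (k in seq_along(roc$thresholds)) {
      t <- roc$thresholds[k]
      expect_equal(roc$tpr[k], mean(inst$values[inst$labels] >= t))
      expect_equal(roc$fpr[k], mean(inst$values[!inst$labels] >= t))
    }
    expect_equal(min(roc$fpr), 0)
    expect_equal(max(roc$fpr), 1)
    expect_equal(min(roc$tpr), 0)
    expect_equal(max(roc$tpr), 1)
  }
})

test_that("trapezoid AUC equals the pairwise Mann-Whitney statistic", {
  set.seed(102)
  for (rep in 1:200) {
    inst <- random_roc_instance(sample(5:30, 1))
    for (dir in c("high_abnormal", "low_abnormal")) {
      roc <- build_roc(inst$values, inst$labels, dir)
      expect_equal(roc_auc(roc)$auc, brute_auc(inst$values, inst$labels, dir),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC and its p-value agree with independent implementations", {
  set.seed(103)
  x <- c(rnorm(40), rnorm(30, 0.8))
  y <- rep(c(FALSE, TRUE), c(40, 30))
  roc <- build_roc(x, y, "high_abnormal")
  a <- roc_auc(roc)
  # pROC as external cross-check of the area
  pr <- pROC::roc(response = y, predictor = x, direction = "<",
                  quiet = TRUE)
  expect_equal(a$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  # tie-corrected normal approximation equals wilcox.test's
  wt <- suppressWarnings(stats::wilcox.test(x[y], x[!y], exact = FALSE,
                                            correct = FALSE))
  expect_equal(a$p, wt$p.value, tolerance = 1e-12)
})

test_that("orientation is corrected and flipping direction mirrors the AUC", {
  set.seed(104)
  inst <- random_roc_instance(25)
  hi <- roc_auc(build_roc(inst$values, inst$labels, "high_abnormal"))$auc
  lo <- roc_auc(build_roc(inst$values, inst$labels, "low_abnormal"))$auc
  expect_equal(hi + lo, 1, tolerance = 1e-12)
  auto <- build_roc(inst$values, inst$labels, "auto")
  expect_gte(roc_auc(auto)$auc, 0.5)
})

test_that("degenerate and invalid inputs are handled", {
  expect_error(build_roc(c(1, 2, 3), c(TRUE, TRUE, TRUE)), "single class")
  expect_warning(roc <- build_roc(rep(2, 6), rep(c(TRUE, FALSE), 3)),
                 "degenerate")
  expect_equal(roc_auc(roc)$auc, 0.5)
})

test_that("perfect separation yields AUC 1 and the midpoint cutoff with J = 1", {
  values <- c(1, 2, 3, 5, 6, 7)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  roc <- build_roc(values, labels, "high_abnormal")
  expect_equal(roc_auc(roc)$auc, 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  cs <- youden_cutoff(roc)
  expect_equal(cs$cutoff, 4)
  expect_equal(cs$youden_j, 1)
  # four-point variant from the operation contract
  roc4 <- build_roc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
                    "high_abnormal")
  expect_true(any(roc4$fpr == 0 & roc4$tpr == 1))
})

test_that("Youden cutoff equals brute-force maximization", {
  set.seed(105)
  for (rep in 1:200) {
    inst <- random_roc_instance(sample(6:25, 1))
    dir <- sample(c("high_abnormal", "low_abnormal"), 1)
    cs <- youden_cutoff(build_roc(inst$values, inst$labels, dir))
    expect_equal(cs$youden_j, brute_youden_j(inst$values, inst$labels, dir),
                 tolerance = 1e-12)
    expect_gte(cs$youden_j, -1)
    expect_lte(cs$youden_j, 1)
  }
})

test_that("Youden ties break toward the threshold labelling fewer abnormal", {
  # J = 0.5 at thresholds 1.5 (3 abnormal) and 3.5 (1 abnormal)
  cs <- youden_cutoff(build_roc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE),
                                "high_abnormal"))
  expect_equal(cs$cutoff, 3.5)
})

test_that("diagnostic metrics reproduce published contingency arithmetic", {
  # post-NACT lymphocyte count row: TP 40, FP 14, FN 4, TN 14
  inst <- values_from_counts(40, 14, 4, 14)
  m <- diagnostic_metrics(inst$values, inst$labels, inst$spec)
  expect_equal(round(m$sensitivity, 3), 0.909)
  expect_equal(round(m$specificity, 3), 0.500)
  expect_equal(truncate2(m$ppv), 74.07)
  expect_equal(truncate2(m$npv), 77.77)
  # post-NACT platelet row: TP 24, FP 7, FN 20, TN 21
  inst <- values_from_counts(24, 7, 20, 21)
  m <- diagnostic_metrics(inst$values, inst$labels, inst$spec)
  expect_equal(truncate2(m$ppv), 77.41)
  expect_equal(truncate2(m$npv), 51.21)
  # perfect classifier
  inst <- values_from_counts(10, 0, 0, 10)
  m <- diagnostic_metrics(inst$values, inst$labels, inst$spec)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 100)
  expect_equal(m$npv, 100)
})

test_that("PPV obeys the Bayes prevalence identity exactly", {
  set.seed(106)
  for (rep in 1:50) {
    inst <- random_roc_instance(30)
    cs <- youden_cutoff(build_roc(inst$values, inst$labels, "high_abnormal"))
    m <- suppressWarnings(diagnostic_metrics(inst$values, inst$labels, cs))
    pi <- mean(inst$labels)
    se <- m$sensitivity
    sp <- m$specificity
    if (!is.na(m$ppv)) {
      expect_equal(m$ppv / 100, se * pi / (se * pi + (1 - sp) * (1 - pi)),
                   tolerance = 1e-12)
    }
  }
})

test_that("undefined predictive values are missing with a warning", {
  vals <- c(0, 0, 0, 0)
  labs <- c(TRUE, TRUE, FALSE, FALSE)
  expect_warning(
    m <- diagnostic_metrics(vals, labs,
                            list(cutoff = 0.5, direction = "high_abnormal")),
    "PPV undefined")
  expect_true(is.na(m$ppv))
})

test_that("truncate2 floors toward zero at the second decimal", {
  expect_equal(truncate2(27 / 33 * 100), 81.81)  # rounding would give 81.82
  expect_equal(truncate2(14 / 18 * 100), 77.77)
  expect_equal(truncate2(50), 50)
  expect_equal(truncate2(35.5012), 35.50)
  expect_equal(truncate2(-1.009), -1.00)
  expect_equal(truncate2(2.0868), 2.08)
})
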