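# A fixed, hand-specified panel of cutoffs used to exercise the scoring
# arithmetic without deriving anything.
fixed_cutoffs <- function() {
  panel <- ppsn_panel()
  cuts <- c(73.40, 14.15, 10.67, 47.65, 41.35, 16.84, 17.35)
  out <- lapply(seq_len(7), function(i) {
    structure(list(marker = panel$marker[i], timepoint = panel$timepoint[i],
                   cutoff = cuts[i], direction = panel$direction[i],
                   youden_j = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, auc = NA_real_, auc_p = NA_real_,
                   n_pos = NA_integer_, n_neg = NA_integer_),
              class = "ppsn_cutoff")
  })
  names(out) <- panel$column
  structure(out, class = "ppsn_panel_cutoffs")
}

# Marker values on the normal (delta = -1) or abnormal (delta = +1) side
# of each fixed cutoff.
pattern_values <- function(pattern) {
  panel <- ppsn_panel()
  cuts <- vapply(fixed_cutoffs(), function(cs) cs$cutoff, 0)
  sgn <- ifelse(panel$direction == "high_abnormal", 1, -1)
  vals <- cuts + ifelse(pattern, sgn, -sgn) * 2
  stats::setNames(as.list(vals), panel$column)
}

test_that("the panel defines exactly the seven published marker/direction pairs", {
  panel <- ppsn_panel()
  expect_equal(nrow(panel), 7)
  expect_equal(sum(panel$timepoint == "pre"), 3)
  expect_equal(sum(panel$timepoint == "post"), 4)
  expect_equal(panel$direction[panel$marker == "neutrophil_pct"],
               rep("high_abnormal", 2))
  expect_true(all(panel$direction[panel$marker != "neutrophil_pct"] ==
                  "low_abnormal"))
  expect_equal(panel$column[panel$marker == "platelet_count"],
               "post_platelet_count")
})

test_that("the score counts abnormal markers over all 128 patterns", {
  cuts <- fixed_cutoffs()
  seen <- integer(0)
  for (code in 0:127) {
    pattern <- as.logical(bitwAnd(code, 2^(0:6)) > 0)
    res <- score_patient(pattern_values(pattern), cuts)
    expect_equal(res$score, sum(pattern))
    expect_equal(res$n_markers_available, 7)
    seen <- union(seen, res$score)
  }
  expect_setequal(seen, 0:7)
})

test_that("boundary values are scored abnormal (inclusive side)", {
  cuts <- fixed_cutoffs()
  vals <- pattern_values(rep(FALSE, 7))
  vals$post_lymphocyte_count <- 16.84  # exactly at the cutoff, low_abnormal
  expect_equal(score_patient(vals, cuts)$score, 1)
})

test_that("score is monotone in each marker's abnormality", {
  cuts <- fixed_cutoffs()
  panel <- ppsn_panel()
  base <- pattern_values(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  s0 <- score_patient(base, cuts)$score
  for (i in seq_len(7)) {
    pushed <- base
    sgn <- if (panel$direction[i] == "high_abnormal") 1 else -1
    pushed[[panel$column[i]]] <- pushed[[panel$column[i]]] + sgn * 5
    expect_gte(score_patient(pushed, cuts)$score, s0)
  }
})

test_that("scoring is invariant to column order and tracks missingness", {
  cuts <- fixed_cutoffs()
  co <- small_cohort(seed = 21)
  s1 <- ppsn_score(co, cuts)
  shuffled <- co[, rev(names(co))]
  s2 <- ppsn_score(shuffled, cuts)
  expect_identical(s1$score, s2$score)

  df <- as.data.frame(co)
  df[1, c("pre_neutrophil_pct", "pre_lymphocyte_pct",
          "pre_lymphocyte_count")] <- NA
  s3 <- ppsn_score(df, cuts)
  expect_equal(s3$n_markers_available[1], 4)
  expect_lte(s3$score[1], 4)
  expect_true(all(s3$score <= s3$n_markers_available))

  df[1, marker_cols <- c("pre_neutrophil_pct", "pre_lymphocyte_pct",
                         "pre_lymphocyte_count", "post_neutrophil_pct",
                         "post_lymphocyte_pct", "post_lymphocyte_count",
                         "post_platelet_count")] <- NA
  expect_error(ppsn_score(df, cuts), "all seven markers missing")
})

test_that("single-indicator example scores one", {
  cuts <- fixed_cutoffs()
  vals <- pattern_values(rep(FALSE, 7))
  vals$pre_neutrophil_pct <- 80  # above 73.40, high_abnormal
  expect_equal(score_patient(vals, cuts)$score, 1)
})

test_that("score threshold derivation mirrors the marker Youden procedure", {
  # perfectly separated scores: 0-3 alive, 4-7 dead
  scores <- rep(0:7, each = 4)
  outcome <- scores >= 4
  thr <- derive_score_threshold(scores, outcome)
  expect_equal(thr$threshold, 4L)
  expect_equal(thr$youden_j, 1)
  expect_equal(thr$auc, 1)

  # identical score distributions in both classes: J = 0, warning
  scores <- rep(c(1, 2, 3), 4)
  outcome <- rep(c(TRUE, FALSE), each = 6)
  expect_warning(thr <- derive_score_threshold(scores, outcome),
                 "no informative threshold")
  expect_equal(thr$youden_j, 0)

  # degenerate: a single distinct score
  expect_error(derive_score_threshold(rep(4, 10),
                                      rep(c(TRUE, FALSE), 5)),
               "degenerate")
})

test_that("classification is high iff score >= threshold", {
  expect_equal(as.character(classify_ppsn(4, 4)), "high")
  expect_equal(as.character(classify_ppsn(3, 4)), "low")
  for (t in 1:7) expect_equal(as.character(classify_ppsn(0, t)), "low")
  thr <- structure(list(threshold = 4L), class = "ppsn_threshold")
  expect_equal(as.character(classify_ppsn(c(0, 3, 4, 7), thr)),
               c("low", "low", "high", "high"))
})

test_that("panel cutoff derivation uses fixed directions and flags bad inputs", {
  co <- small_cohort(seed = 22)
  cuts <- derive_panel_cutoffs(co)
  expect_s3_class(cuts, "ppsn_panel_cutoffs")
  expect_named(cuts, ppsn_panel()$column)
  for (i in seq_len(7)) {
    expect_equal(cuts[[i]]$direction, ppsn_panel()$direction[i])
    expect_gte(cuts[[i]]$auc, 0)
    expect_lte(cuts[[i]]$auc, 1)
  }
  df <- as.data.frame(co)
  df$death <- TRUE
  expect_error(derive_panel_cutoffs(as_cohort(df)), "pre_neutrophil_pct")
})

test_that("a pure-noise marker has AUC near one half", {
  set.seed(23)
  aucs <- replicate(30, {
    co <- generate_cohort(ppsn_sim_config(latent_effect = 0,
                                          seed = sample.int(1e6, 1)))
    cs <- derive_panel_cutoffs(co)
    mean(vapply(cs, function(x) x$auc, 0))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
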