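# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths.

# AUC by exhaustive pair enumeration (ties count 1/2).
brute_auc <- function(values, labels, direction = "high_abnormal") {
  pos <- values[labels]
  neg <- values[!labels]
  cmp <- outer(pos, neg, function(a, b) {
    if (direction == "high_abnormal") (a > b) + 0.5 * (a == b)
    else (a < b) + 0.5 * (a == b)
  })
  mean(cmp)
}

# Best Youden index by scanning every midpoint plus outer sentinels.
brute_youden_j <- function(values, labels, direction = "high_abnormal") {
  v <- sort(unique(values))
  thr <- if (length(v) == 1L) c(v - 1, v + 1)
         else c(v[1] - 1, (v[-length(v)] + v[-1]) / 2, v[length(v)] + 1)
  best <- -Inf
  for (t in thr) {
    abn <- if (direction == "high_abnormal") values >= t else values <= t
    j <- mean(abn[labels]) - mean(abn[!labels])
    if (j > best) best <- j
  }
  best
}

# Log-rank chi-square from first principles (hypergeometric moments).
brute_logrank_chi2 <- function(time, event, group) {
  group <- factor(group)
  g1 <- levels(group)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# A random ROC instance with ties.
random_roc_instance <- function(n = 20) {
  values <- sample(seq(0, 10, by = 0.5), n, replace = TRUE)
  labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
  if (all(labels)) labels[1] <- FALSE
  if (!any(labels)) labels[1] <- TRUE
  list(values = values, labels = labels)
}

# Build marker values realizing given 2x2 counts at a unit cutoff
# (abnormal = value >= 1).
values_from_counts <- function(tp, fp, fn, tn) {
  list(values = c(rep(1, tp + fp), rep(0, fn + tn)),
       labels = c(rep(TRUE, tp), rep(FALSE, fp),
                  rep(TRUE, fn), rep(FALSE, tn)),
       spec = list(cutoff = 0.5, direction = "high_abnormal"))
}

# Small deterministic cohort for I/O tests (no missingness so tests can
# inject their own).
small_cohort <- function(seed = 11, n = 40) {
  generate_cohort(ppsn_sim_config(n = n, missing_pre_fraction = 0,
                                  seed = seed))
}
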