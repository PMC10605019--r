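#' Build an empirical ROC curve
#'
#' Constructs the receiver operating characteristic curve of a continuous
#' marker against a binary event.  Candidate thresholds are the midpoints
#' between consecutive distinct observed values, plus one sentinel below
#' the minimum and one above the maximum, so that no observed value ever
#' falls on a threshold.  The abnormal (test-positive) side is inclusive:
#' `value >= t` when high values are abnormal, `value <= t` when low
#' values are abnormal.
#'
#' With `direction = "auto"` the orientation giving AUC >= 0.5 is chosen.
#'
#' @param values numeric marker values (pairs with a missing value or
#'   missing label are dropped).
#' @param labels logical event indicator (e.g. death), same length.
#' @param direction `"auto"`, `"high_abnormal"` or `"low_abnormal"`.
#' @return An object of class `ppsn_roc` with elements `thresholds`,
#'   `tpr`, `fpr`, `direction`, `n_pos`, `n_neg` and the complete-case
#'   `values`/`labels` used.
#' @export
build_roc <- function(values, labels,
                      direction = c("auto", "high_abnormal", "low_abnormal")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels))
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  if (!any(is.finite(values)) || length(values) == 0L) {
    stop("no usable (value, label) pairs")
  }
  if (any(!is.finite(values))) stop("marker values must be finite")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: labels contain a single class")
  }
  v <- sort(unique(values))
  degenerate <- length(v) == 1L
  if (degenerate) {
    warning("all marker values identical: degenerate ROC with AUC 0.5")
    thr <- c(v - 1, v + 1)
  } else {
    mid <- (v[-length(v)] + v[-1]) / 2
    thr <- c(v[1] - 1, mid, v[length(v)] + 1)
  }
  if (direction == "auto") {
    hi <- roc_points(values, labels, thr, "high_abnormal")
    direction <- if (trapezoid_area(hi$fpr, hi$tpr) >= 0.5)
      "high_abnormal" else "low_abnormal"
  }
  pts <- roc_points(values, labels, thr, direction)
  structure(
    list(thresholds = pts$thresholds, tpr = pts$tpr, fpr = pts$fpr,
         direction = direction, n_pos = n_pos, n_neg = n_neg,
         values = values, labels = labels, degenerate = degenerate),
    class = "ppsn_roc")
}

# Sensitivity / 1-specificity at each threshold, ordered so fpr runs 0 -> 1.
roc_points <- function(values, labels, thresholds, direction) {
  abnormal <- function(t) {
    if (direction == "high_abnormal") values >= t else values <= t
  }
  tpr <- vapply(thresholds, function(t) mean(abnormal(t)[labels]), 0)
  fpr <- vapply(thresholds, function(t) mean(abnormal(t)[!labels]), 0)
  ord <- order(fpr, tpr)
  list(thresholds = thresholds[ord], tpr = tpr[ord], fpr = fpr[ord])
}

trapezoid_area <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  x <- fpr[ord]; y <- tpr[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area under the ROC curve with a p-value
#'
#' Trapezoidal area over (1-specificity, sensitivity).  Because candidate
#' thresholds sit strictly between distinct observed values, the trapezoid
#' rule counts tied value pairs as 1/2, so the area equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`.  The p-value for
#' AUC = 0.5 comes from the tie-corrected normal approximation of U.
#'
#' @param roc a `ppsn_roc` from [build_roc()].
#' @return List with `auc`, `p`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "ppsn_roc"))
  area <- trapezoid_area(roc$fpr, roc$tpr)
  list(auc = area, p = mann_whitney_p(roc$values, roc$labels),
       n_pos = roc$n_pos, n_neg = roc$n_neg)
}

# Two-sided p for U via the normal approximation with tie correction.
mann_whitney_p <- function(values, labels) {
  n1 <- sum(labels); n0 <- sum(!labels); n <- n1 + n0
  r <- rank(values)
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n0 / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u - n1 * n0 / 2) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Youden-optimal cutoff
#'
#' Scans every candidate threshold of the curve and returns the one
#' maximizing the Youden index J = sensitivity + specificity - 1.  Ties on
#' J are broken toward the threshold classifying fewer subjects as
#' abnormal (the more specific rule).
#'
#' @param roc a `ppsn_roc`.
#' @param marker optional marker name recorded in the result.
#' @param timepoint optional timepoint (`"pre"`/`"post"`) recorded in the
#'   result.
#' @return An object of class `ppsn_cutoff`: `marker`, `timepoint`,
#'   `cutoff`, `direction`, `youden_j`, `sensitivity`, `specificity`,
#'   `auc`, `auc_p`, `n_pos`, `n_neg`.
#' @export
youden_cutoff <- function(roc, marker = NA_character_,
                          timepoint = NA_character_) {
  stopifnot(inherits(roc, "ppsn_roc"))
  j <- roc$tpr - roc$fpr
  n_abn <- vapply(roc$thresholds, function(t) {
    if (roc$direction == "high_abnormal") sum(roc$values >= t)
    else sum(roc$values <= t)
  }, 0L)
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  pick <- cand[which.min(n_abn[cand])]
  a <- roc_auc(roc)
  structure(
    list(marker = marker, timepoint = timepoint,
         cutoff = roc$thresholds[pick], direction = roc$direction,
         youden_j = j[pick], sensitivity = roc$tpr[pick],
         specificity = 1 - roc$fpr[pick],
         auc = a$auc, auc_p = a$p, n_pos = roc$n_pos, n_neg = roc$n_neg),
    class = "ppsn_cutoff")
}

#' @export
print.ppsn_cutoff <- function(x, ...) {
  cat(sprintf(
    "%s (%s): cutoff %.4g [%s], J = %.3f (Se %.3f, Sp %.3f), AUC %.3f (p = %.3g)\n",
    ifelse(is.na(x$marker), "marker", x$marker),
    ifelse(is.na(x$timepoint), "-", x$timepoint),
    x$cutoff, x$direction, x$youden_j, x$sensitivity, x$specificity,
    x$auc, x$auc_p))
  invisible(x)
}

#' Diagnostic metrics at a cutoff
#'
#' Dichotomizes the marker at `spec$cutoff` (abnormal side inclusive, per
#' `spec$direction`) against the event labels and returns the exact 2x2
#' table with sensitivity, specificity (proportions) and PPV, NPV
#' (percentages).  A zero predicted-positive (or predicted-negative)
#' margin makes PPV (NPV) undefined: reported missing with a warning.
#'
#' @param values numeric marker values.
#' @param labels logical event indicator.
#' @param spec a `ppsn_cutoff` (or any list with `cutoff` and `direction`).
#' @return List of class `ppsn_diag`: `table` (a `ppsn_table2x2`),
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
diagnostic_metrics <- function(values, labels, spec) {
  stopifnot(length(values) == length(labels))
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (sum(labels) == 0L || sum(!labels) == 0L) {
    stop("diagnostic metrics need both event and non-event subjects")
  }
  abnormal <- if (spec$direction == "high_abnormal") values >= spec$cutoff
              else values <= spec$cutoff
  tab <- contingency_2x2(abnormal, labels)
  metrics_from_table(tab)
}

metrics_from_table <- function(tab) {
  tp <- tab$tp; fp <- tab$fp; fn <- tab$fn; tn <- tab$tn
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  if (tp + fp == 0L) {
    warning("no predicted positives: PPV undefined")
    ppv <- NA_real_
  } else ppv <- 100 * tp / (tp + fp)
  if (tn + fn == 0L) {
    warning("no predicted negatives: NPV undefined")
    npv <- NA_real_
  } else npv <- 100 * tn / (tn + fn)
  structure(list(table = tab, sensitivity = se, specificity = sp,
                 ppv = ppv, npv = npv),
            class = "ppsn_diag")
}

#' Truncate a value to two decimals for display
#'
#' Floors toward zero at the second decimal (81.8181... -> 81.81, not
#' 81.82).  This is the display convention for predictive values and odds
#' ratios; it is never used in computation.  A small epsilon guards
#' against binary representation error (so 47.65 stays 47.65).
#'
#' @param x numeric.
#' @return `x` truncated to two decimals.
#' @export
truncate2 <- function(x) {
  trunc(x * 100 + sign(x) * 1e-9) / 100
}
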