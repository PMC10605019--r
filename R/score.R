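#' The seven PPSN marker definitions
#'
#' The composite score counts abnormal values among seven peripheral-blood
#' parameters: neutrophil %, lymphocyte % and lymphocyte count at both the
#' pre-treatment and post-NACT timepoints, plus the post-NACT platelet
#' count.  Elevated neutrophils are abnormal; decreased lymphocytes
#' (proportion and count) and decreased platelets are abnormal.
#'
#' @return Data frame with columns `column` (cohort column name),
#'   `marker`, `timepoint`, `direction`.
#' @export
ppsn_panel <- function() {
  data.frame(
    column = c("pre_neutrophil_pct", "pre_lymphocyte_pct",
               "pre_lymphocyte_count",
               "post_neutrophil_pct", "post_lymphocyte_pct",
               "post_lymphocyte_count", "post_platelet_count"),
    marker = c("neutrophil_pct", "lymphocyte_pct", "lymphocyte_count",
               "neutrophil_pct", "lymphocyte_pct", "lymphocyte_count",
               "platelet_count"),
    timepoint = c("pre", "pre", "pre", "post", "post", "post", "post"),
    direction = c("high_abnormal", "low_abnormal", "low_abnormal",
                  "high_abnormal", "low_abnormal", "low_abnormal",
                  "low_abnormal"),
    stringsAsFactors = FALSE)
}

#' Derive Youden-optimal cutoffs for the seven PPSN markers
#'
#' Runs the ROC / Youden procedure per marker against the mortality
#' indicator, on that marker's complete cases, with the abnormality
#' direction fixed by [ppsn_panel()].  Per-marker denominators may differ
#' when some records lack a timepoint (complete-case per marker).
#'
#' @param cohort a `ppsn_cohort`.
#' @param outcome logical event vector (defaults to `cohort$death`).
#' @return Object of class `ppsn_panel_cutoffs`: a named list of seven
#'   `ppsn_cutoff` entries keyed by cohort column name.
#' @export
derive_panel_cutoffs <- function(cohort, outcome = cohort$death) {
  panel <- ppsn_panel()
  stopifnot(length(outcome) == nrow(cohort))
  cutoffs <- vector("list", nrow(panel))
  names(cutoffs) <- panel$column
  for (i in seq_len(nrow(panel))) {
    col <- panel$column[i]
    v <- cohort[[col]]
    keep <- !is.na(v) & !is.na(outcome)
    if (sum(outcome[keep]) < 2L || sum(!outcome[keep]) < 2L) {
      stop(sprintf("marker '%s': fewer than 2 complete cases in a class", col))
    }
    roc <- build_roc(v[keep], outcome[keep], direction = panel$direction[i])
    cutoffs[[col]] <- youden_cutoff(roc, marker = panel$marker[i],
                                    timepoint = panel$timepoint[i])
  }
  structure(cutoffs, class = "ppsn_panel_cutoffs")
}

#' @export
print.ppsn_panel_cutoffs <- function(x, ...) {
  cat("PPSN panel cutoffs:\n")
  for (cs in x) print(cs)
  invisible(x)
}

#' Score patients on the 0-7 PPSN scale
#'
#' Counts, per patient, how many of the seven markers fall on the
#' abnormal side of their cutoff (inclusive).  A missing marker
#' contributes 0 to the score and decrements `n_markers_available`; a
#' patient with all seven markers missing is an error.
#'
#' @param cohort a `ppsn_cohort` (or any data frame with the seven marker
#'   columns).
#' @param cutoffs a `ppsn_panel_cutoffs`.
#' @return Data frame: `patient_id`, `score` (0-7),
#'   `n_markers_available` (0-7).
#' @export
ppsn_score <- function(cohort, cutoffs) {
  stopifnot(inherits(cutoffs, "ppsn_panel_cutoffs"))
  panel <- ppsn_panel()
  abn <- matrix(NA, nrow = nrow(cohort), ncol = nrow(panel),
                dimnames = list(NULL, panel$column))
  for (col in panel$column) {
    cs <- cutoffs[[col]]
    v <- cohort[[col]]
    abn[, col] <- if (cs$direction == "high_abnormal") v >= cs$cutoff
                  else v <= cs$cutoff
  }
  available <- rowSums(!is.na(abn))
  if (any(available == 0L)) {
    stop("patient(s) with all seven markers missing: ",
         paste(cohort$patient_id[available == 0L], collapse = ", "))
  }
  score <- rowSums(abn, na.rm = TRUE)
  data.frame(patient_id = as.character(cohort$patient_id),
             score = as.integer(score),
             n_markers_available = as.integer(available),
             stringsAsFactors = FALSE)
}

#' Score a single patient
#'
#' @param markers named list or vector of the seven marker values (names
#'   as in `ppsn_panel()$column`); missing entries allowed.
#' @param cutoffs a `ppsn_panel_cutoffs`.
#' @return List: `score`, `n_markers_available`.
#' @export
score_patient <- function(markers, cutoffs) {
  row <- as.data.frame(as.list(markers))
  for (col in setdiff(ppsn_panel()$column, names(row))) row[[col]] <- NA_real_
  row$patient_id <- "patient"
  res <- ppsn_score(row, cutoffs)
  list(score = res$score, n_markers_available = res$n_markers_available)
}

#' Derive the high/low threshold on the PPSN score
#'
#' Applies the same Youden procedure to the integer score's ROC against
#' the event (scores high-abnormal) and reports the smallest integer `t`
#' such that "high" is `score >= t`.  Candidate ROC thresholds are
#' midpoints between observed scores, so `t` is the ceiling of the
#' Youden-optimal midpoint.
#'
#' @param scores integer 0-7 scores.
#' @param outcome logical event vector.
#' @return List of class `ppsn_threshold`: `threshold` (integer),
#'   `cutoff` (the raw midpoint), `youden_j`, `sensitivity`,
#'   `specificity`, `auc`, `auc_p`.
#' @export
derive_score_threshold <- function(scores, outcome) {
  keep <- !is.na(scores) & !is.na(outcome)
  scores <- scores[keep]; outcome <- as.logical(outcome[keep])
  if (length(unique(scores)) < 2L) {
    stop("degenerate score distribution: a single distinct score")
  }
  roc <- build_roc(scores, outcome, direction = "high_abnormal")
  cs <- youden_cutoff(roc, marker = "ppsn_score")
  if (cs$youden_j <= 0) {
    warning("no informative threshold: Youden J = 0")
  }
  structure(
    list(threshold = as.integer(ceiling(cs$cutoff)), cutoff = cs$cutoff,
         youden_j = cs$youden_j, sensitivity = cs$sensitivity,
         specificity = cs$specificity, auc = cs$auc, auc_p = cs$auc_p),
    class = "ppsn_threshold")
}

#' Classify scores as high or low PPSN
#'
#' High means `score >= threshold` (with the published threshold 4, high
#' PPSN is a score of 4-7 and low PPSN 0-3).
#'
#' @param score integer score(s).
#' @param threshold integer threshold (or a `ppsn_threshold`).
#' @return Factor with levels `low`, `high`.
#' @export
classify_ppsn <- function(score, threshold) {
  if (inherits(threshold, "ppsn_threshold")) threshold <- threshold$threshold
  factor(ifelse(score >= threshold, "high", "low"), levels = c("low", "high"))
}
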