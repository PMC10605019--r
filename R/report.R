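#' Published per-marker summary statistics
#'
#' The printed ROC summary for the seven panel markers against mortality:
#' AUC with its p-value, the Youden-optimal cutoff, sensitivity and
#' specificity (3 decimals), and PPV/NPV (percentages, truncated to 2
#' decimals), together with the complete-case denominators the metrics
#' were computed on (43 dead / 24 alive pre-treatment, 44 / 28
#' post-NACT).  These published values are inputs to the worked-example
#' harness, which reconstructs the underlying 2x2 counts from them.
#'
#' @return Data frame, one row per marker.
#' @export
published_marker_table <- function() {
  data.frame(
    column = ppsn_panel()$column,
    marker = ppsn_panel()$marker,
    timepoint = ppsn_panel()$timepoint,
    auc = c(0.655, 0.657, 0.677, 0.669, 0.672, 0.688, 0.657),
    p = c(0.036, 0.034, 0.017, 0.016, 0.015, 0.007, 0.026),
    cutoff = c(73.40, 14.15, 10.67, 47.65, 41.35, 16.84, 17.35),
    sensitivity = c(0.628, 0.442, 0.535, 0.614, 0.727, 0.909, 0.545),
    specificity = c(0.750, 0.917, 0.875, 0.679, 0.571, 0.500, 0.750),
    ppv = c(81.81, 90.47, 88.46, 75.00, 72.72, 74.07, 77.41),
    npv = c(52.94, 47.82, 51.21, 52.77, 57.14, 77.77, 51.21),
    n_dead = c(43, 43, 43, 44, 44, 44, 44),
    n_alive = c(24, 24, 24, 28, 28, 28, 28),
    stringsAsFactors = FALSE)
}

#' Published univariate odds ratios for mortality
#'
#' The printed univariate association table: each marker dichotomized at
#' its cutoff, plus FIGO stage IV versus II-III.  Odds ratios and Wald
#' 95% bounds are printed truncated to two decimals; `p` is the printed
#' p-value as text (`"<0.001"` for values below a thousandth).
#'
#' @return Data frame, one row per variable.
#' @export
published_or_table <- function() {
  data.frame(
    variable = c("figo_stage_iv", ppsn_panel()$column),
    or = c(2.09, 5.06, 8.70, 8.05, 3.35, 3.55, 10.00, 3.60),
    ci_low = c(0.70, 1.66, 1.81, 2.08, 1.23, 1.30, 2.81, 1.27),
    ci_high = c(6.24, 15.38, 41.76, 31.05, 9.10, 9.66, 35.50, 10.19),
    p = c("0.184", "0.004", "0.007", "0.002", "0.018", "0.013",
          "<0.001", "0.016"),
    stringsAsFactors = FALSE)
}

#' Published FIGO stage by outcome counts
#'
#' Stage distribution of the cohort by vital status (live: one stage II,
#' 21 stage III, 6 stage IV; dead: 28 stage III, 16 stage IV), used to
#' form the stage-IV exposure 2x2.
#'
#' @return A `ppsn_table2x2` for stage IV vs death.
#' @export
published_figo_table <- function() {
  table2x2(tp = 16, fp = 6, fn = 28, tn = 22)
}

#' Reconstruct per-marker 2x2 counts from published summary statistics
#'
#' Inverts the printed sensitivity/specificity through the complete-case
#' group sizes: TP = round(Se * n_dead), TN = round(Sp * n_alive), with
#' FP and FN as the complements.
#'
#' @param published data frame in the shape of
#'   [published_marker_table()].
#' @return The input with integer columns `tp`, `fp`, `fn`, `tn`
#'   appended.
#' @export
reconstruct_published_counts <- function(published = published_marker_table()) {
  published$tp <- as.integer(round(published$sensitivity * published$n_dead))
  published$tn <- as.integer(round(published$specificity * published$n_alive))
  published$fn <- published$n_dead - published$tp
  published$fp <- published$n_alive - published$tn
  published
}

#' Re-derive the published worked examples
#'
#' Reconstructs each marker's 2x2 table from the published sensitivity /
#' specificity and complete-case group sizes, then recomputes sensitivity,
#' specificity, PPV, NPV, the cross-product odds ratio with its Wald 95%
#' interval and p-value, truncates/rounds for display, and compares
#' against every published value; the FIGO stage IV odds ratio is checked
#' from the published stage-by-outcome counts.  One row per target with
#' the recomputed value, the published value, the discrepancy and a
#' pass flag.
#'
#' @param counts reconstructed count table from
#'   [reconstruct_published_counts()]; pass a perturbed copy to verify that
#'   the harness detects discrepancies.
#' @return Data frame of class `ppsn_worked_examples`.
#' @export
reproduce_worked_examples <- function(counts = reconstruct_published_counts()) {
  or_pub <- published_or_table()
  rows <- list()
  add <- function(target, published, actual, display) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, published = published, recomputed = actual,
      display = display, delta = display - published,
      pass = isTRUE(all.equal(display, published, tolerance = 1e-12)),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    tab <- table2x2(tp = row$tp, fp = row$fp, fn = row$fn, tn = row$tn)
    m <- metrics_from_table(tab)
    key <- paste0(row$timepoint, "_", row$marker)
    add(paste0(key, "_sensitivity"), row$sensitivity, m$sensitivity,
        round(m$sensitivity, 3))
    add(paste0(key, "_specificity"), row$specificity, m$specificity,
        round(m$specificity, 3))
    add(paste0(key, "_ppv"), row$ppv, m$ppv, truncate2(m$ppv))
    add(paste0(key, "_npv"), row$npv, m$npv, truncate2(m$npv))
    orr <- odds_ratio_wald(tab)
    pub <- or_pub[or_pub$variable == row$column, ]
    add(paste0(key, "_or"), pub$or, orr$or_point, truncate2(orr$or_point))
    add(paste0(key, "_or_ci_low"), pub$ci_low, orr$ci_low,
        truncate2(orr$ci_low))
    add(paste0(key, "_or_ci_high"), pub$ci_high, orr$ci_high,
        truncate2(orr$ci_high))
    p_pass <- if (pub$p == "<0.001") orr$p < 0.001
              else isTRUE(all.equal(round(orr$p, 3), as.numeric(pub$p)))
    rows[[length(rows) + 1L]] <- data.frame(
      target = paste0(key, "_or_p"),
      published = ifelse(pub$p == "<0.001", 0.001, as.numeric(pub$p)),
      recomputed = orr$p, display = round(orr$p, 3),
      delta = NA_real_, pass = p_pass, stringsAsFactors = FALSE)
  }
  figo <- odds_ratio_wald(published_figo_table())
  pub <- or_pub[or_pub$variable == "figo_stage_iv", ]
  add("figo_iv_or", pub$or, figo$or_point, truncate2(figo$or_point))
  add("figo_iv_or_ci_low", pub$ci_low, figo$ci_low, truncate2(figo$ci_low))
  add("figo_iv_or_ci_high", pub$ci_high, figo$ci_high,
      truncate2(figo$ci_high))
  add("figo_iv_or_p", as.numeric(pub$p), figo$p, round(figo$p, 3))
  out <- do.call(rbind, rows)
  class(out) <- c("ppsn_worked_examples", "data.frame")
  out
}

#' @export
print.ppsn_worked_examples <- function(x, ...) {
  cat(sprintf("Worked-example checks: %d/%d pass\n", sum(x$pass), nrow(x)))
  if (any(!x$pass)) {
    cat("failing targets:\n")
    print(as.data.frame(x[!x$pass, ]))
  }
  invisible(x)
}

#' Run the full PPSN analysis on a cohort
#'
#' End-to-end pipeline: per-marker complete cases, Youden cutoffs against
#' mortality, PPSN scoring and score threshold, univariate / multivariate
#' mortality associations, horizon-restricted (3-year, 5-year, total)
#' analyses of OS and PFS with Kaplan-Meier curves and log-rank tests by
#' PPSN class, and TIL group comparisons when TIL data are present.
#' Deterministic given the cohort and options.
#'
#' @param cohort a `ppsn_cohort`.
#' @param multivariate_predictors cohort marker columns entering the
#'   multivariate mortality model (dichotomized at their derived
#'   cutoffs).
#' @param verbose log per-stage sample sizes to standard error.
#' @return List of class `ppsn_report` with elements `markers`, `scores`,
#'   `threshold`, `mortality`, `horizons`, `km`, `tils` (or `NULL` with a
#'   notice), `provenance`.
#' @export
run_full_analysis <- function(cohort,
                              multivariate_predictors =
                                c("pre_lymphocyte_count",
                                  "post_lymphocyte_count"),
                              verbose = FALSE) {
  stopifnot(inherits(cohort, "ppsn_cohort"))
  note <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cutoffs <- stage("derive_panel_cutoffs", derive_panel_cutoffs(cohort))
  markers <- stage("markers", {
    do.call(rbind, lapply(ppsn_panel()$column, function(col) {
      cs <- cutoffs[[col]]
      keep <- !is.na(cohort[[col]]) & !is.na(cohort$death)
      dm <- diagnostic_metrics(cohort[[col]][keep], cohort$death[keep], cs)
      note("markers", sprintf("%s: n=%d", col, sum(keep)))
      data.frame(column = col, marker = cs$marker, timepoint = cs$timepoint,
                 n_dead = cs$n_pos, n_alive = cs$n_neg,
                 auc = cs$auc, auc_p = cs$auc_p, cutoff = cs$cutoff,
                 sensitivity = dm$sensitivity, specificity = dm$specificity,
                 ppv = dm$ppv, npv = dm$npv,
                 ppv_display = truncate2(dm$ppv),
                 npv_display = truncate2(dm$npv),
                 stringsAsFactors = FALSE)
    }))
  })

  scores <- stage("ppsn_score", ppsn_score(cohort, cutoffs))
  threshold <- stage("derive_score_threshold",
                     derive_score_threshold(scores$score, cohort$death))
  scores$class <- classify_ppsn(scores$score, threshold)
  note("score", sprintf("threshold %d, %d high / %d low",
                        threshold$threshold, sum(scores$class == "high"),
                        sum(scores$class == "low")))

  mortality <- stage("mortality", {
    uni <- lapply(ppsn_panel()$column, function(col) {
      cs <- cutoffs[[col]]
      abn <- if (cs$direction == "high_abnormal")
        cohort[[col]] >= cs$cutoff else cohort[[col]] <= cs$cutoff
      odds_ratio_wald(contingency_2x2(abn, cohort$death))
    })
    names(uni) <- ppsn_panel()$column
    uni$figo_stage_iv <-
      odds_ratio_wald(contingency_2x2(cohort$figo_stage == 4, cohort$death))
    multi <- NULL
    if (length(multivariate_predictors) > 0L) {
      x <- sapply(multivariate_predictors, function(col) {
        cs <- cutoffs[[col]]
        as.numeric(if (cs$direction == "high_abnormal")
          cohort[[col]] >= cs$cutoff else cohort[[col]] <= cs$cutoff)
      })
      keep <- stats::complete.cases(x) & !is.na(cohort$death)
      design <- cbind(intercept = 1, x[keep, , drop = FALSE])
      multi <- logistic_fit(design, cohort$death[keep])
      note("mortality", sprintf("multivariate n=%d", sum(keep)))
    }
    list(univariate = uni, multivariate = multi)
  })

  endpoints <- list(
    os = list(time = cohort$os_days, event = cohort$death),
    pfs = list(time = cohort$pfs_days,
               event = cohort$recurrence | cohort$death))
  horizon_labels <- c("3y", "5y", "total")

  horizons <- stage("horizons", {
    out <- list()
    for (h in horizon_labels) {
      hb <- horizon_binary_outcome(endpoints$os$time, endpoints$os$event,
                                   horizon_days(h))
      note("horizons", sprintf("%s OS: %d excluded", h, hb$n_excluded))
      vars <- list(
        figo_stage_iv = cohort$figo_stage == 4,
        surgical_outcome_others = cohort$surgical_outcome != "complete",
        ppsn_high = scores$class == "high")
      uni <- lapply(vars, function(v)
        odds_ratio_wald(contingency_2x2(v, hb$outcome)))
      keep <- !is.na(hb$outcome)
      design <- cbind(intercept = 1,
                      ppsn_high = as.numeric(vars$ppsn_high[keep]))
      # separation is a legitimate small-sample outcome at a horizon:
      # record it instead of failing the whole report
      multi <- tryCatch(logistic_fit(design, hb$outcome[keep]),
                        error = function(e)
                          structure(list(error = conditionMessage(e)),
                                    class = "ppsn_logit_failure"))
      out[[h]] <- list(univariate = uni, multivariate = multi,
                       n_excluded = hb$n_excluded)
    }
    out
  })

  km <- stage("km", {
    out <- list()
    for (ep in names(endpoints)) {
      for (h in horizon_labels) {
        r <- restrict_horizon(endpoints[[ep]]$time, endpoints[[ep]]$event,
                              horizon_days(h))
        keep <- !is.na(r$time) & !is.na(r$event)
        grp <- scores$class
        curves <- lapply(c(low = "low", high = "high"), function(g)
          km_estimate(r$time[keep & grp == g], r$event[keep & grp == g]))
        lr <- log_rank(r$time[keep], r$event[keep], grp[keep])
        out[[paste(ep, h, sep = "_")]] <-
          list(curves = curves, log_rank = lr, n = sum(keep))
      }
    }
    out
  })

  tils <- NULL
  if (all(til_columns() %in% names(cohort)) &&
      any(!is.na(cohort[[til_columns()[1]]]))) {
    tils <- stage("tils", {
      comparisons <- lapply(stats::setNames(nm = til_columns()),
                            function(col) {
        compare_groups(cohort[[col]][scores$class == "low"],
                       cohort[[col]][scores$class == "high"])
      })
      correlations <- lapply(
        stats::setNames(nm = c("cd3_tils", "cd8_tils")),
        function(col) rank_correlation(cohort[[col]],
                                       cohort$pre_lymphocyte_count))
      n_til <- sum(!is.na(cohort[[til_columns()[1]]]))
      note("tils", sprintf("n=%d", n_til))
      list(comparisons = comparisons, correlations = correlations,
           n = n_til)
    })
  } else {
    note("tils", "no TIL data: block omitted")
  }

  structure(
    list(markers = markers, cutoffs = cutoffs, scores = scores,
         threshold = threshold, mortality = mortality, horizons = horizons,
         km = km, tils = tils,
         provenance = list(
           n = nrow(cohort), provenance = attr(cohort, "provenance"),
           package_version = as.character(utils::packageVersion("ppsn")))),
    class = "ppsn_report")
}

#' @export
print.ppsn_report <- function(x, ...) {
  cat(sprintf("PPSN analysis report: n = %d (%s)\n", x$provenance$n,
              x$provenance$provenance))
  cat(sprintf("  score threshold: %d (J = %.3f, AUC = %.3f)\n",
              x$threshold$threshold, x$threshold$youden_j, x$threshold$auc))
  cat(sprintf("  markers with AUC p < 0.05: %d/7\n",
              sum(x$markers$auc_p < 0.05)))
  cat(sprintf("  total-OS log-rank p by PPSN class: %.3g\n",
              x$km$os_total$log_rank$p))
  invisible(x)
}
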