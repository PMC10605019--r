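#' Cross-tabulate a binary exposure against a binary outcome
#'
#' Builds the 2x2 table in exposure-by-outcome layout: `tp` = exposed
#' events, `fp` = exposed non-events, `fn` = unexposed events, `tn` =
#' unexposed non-events.  Pairs with a missing value in either variable
#' are dropped.
#'
#' @param exposure logical vector (abnormal / test-positive).
#' @param outcome logical vector (event, e.g. death).
#' @return An object of class `ppsn_table2x2` with integer cells `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
contingency_2x2 <- function(exposure, outcome) {
  stopifnot(length(exposure) == length(outcome), length(exposure) >= 1L)
  exposure <- as.logical(exposure); outcome <- as.logical(outcome)
  keep <- !is.na(exposure) & !is.na(outcome)
  if (!any(keep)) stop("empty 2x2 table: all pairs missing")
  exposure <- exposure[keep]; outcome <- outcome[keep]
  table2x2(tp = sum(exposure & outcome), fp = sum(exposure & !outcome),
           fn = sum(!exposure & outcome), tn = sum(!exposure & !outcome))
}

#' @rdname contingency_2x2
#' @param tp,fp,fn,tn non-negative cell counts (for building a table
#'   directly, e.g. from published summary statistics).
#' @export
table2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(cells >= 0), sum(cells) > 0)
  structure(as.list(cells), class = "ppsn_table2x2")
}

#' @export
print.ppsn_table2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Odds ratio with Wald confidence interval
#'
#' Cross-product odds ratio OR = (tp * tn) / (fp * fn) with the 95% Wald
#' interval exp(ln OR +/- 1.96 * SE), SE = sqrt(1/tp + 1/fp + 1/fn + 1/tn),
#' and the two-sided Wald p-value.  If any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell (flagged via
#' `corrected`); two zero cells on the same diagonal leave the OR
#' undefined and raise an error.
#'
#' @param table a `ppsn_table2x2`.
#' @return List of class `ppsn_or`: `or_point`, `ci_low`, `ci_high`, `p`,
#'   `corrected`, `table`.
#' @export
odds_ratio_wald <- function(table) {
  stopifnot(inherits(table, "ppsn_table2x2"))
  cells <- c(table$tp, table$fp, table$fn, table$tn)
  if ((cells[1] == 0 && cells[4] == 0) || (cells[2] == 0 && cells[3] == 0)) {
    stop("odds ratio undefined: two zero cells on a diagonal")
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z_crit <- 1.96
  z <- log_or / se
  structure(
    list(or_point = exp(log_or),
         ci_low = exp(log_or - z_crit * se),
         ci_high = exp(log_or + z_crit * se),
         p = 2 * stats::pnorm(-abs(z)),
         corrected = corrected, table = table),
    class = "ppsn_or")
}

#' @export
print.ppsn_or <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g%s\n",
              x$or_point, x$ci_low, x$ci_high, x$p,
              if (x$corrected) " [0.5 continuity correction]" else ""))
  invisible(x)
}

#' Logistic regression fit
#'
#' Maximum-likelihood logistic regression via iteratively reweighted
#' least squares (through `stats::glm.fit`), with per-coefficient Wald
#' z-tests.  The caller supplies the design matrix including the
#' intercept column.  For a single binary predictor, `exp(coef)` with its
#' Wald interval reproduces [odds_ratio_wald()] exactly.
#'
#' @param design numeric design matrix (n x p), intercept included.
#' @param outcome logical outcome vector of length n.
#' @param tol IRLS convergence tolerance on the deviance.
#' @param max_iter maximum IRLS iterations.
#' @return List of class `ppsn_logit`: `coefficients`, `covariance`,
#'   `se`, `z`, `p`, `or` (`exp(coef)` with 95% Wald bounds),
#'   `converged`, `n_iter`.
#' @export
logistic_fit <- function(design, outcome, tol = 1e-10, max_iter = 50L) {
  design <- as.matrix(design)
  outcome <- as.logical(outcome)
  stopifnot(nrow(design) == length(outcome), !anyNA(design), !anyNA(outcome))
  if (all(outcome) || all(!outcome)) {
    stop("outcome is constant: logistic model undefined")
  }
  fit <- stats::glm.fit(x = design, y = as.numeric(outcome),
                        family = stats::binomial(),
                        control = stats::glm.control(epsilon = tol,
                                                     maxit = max_iter))
  if (!fit$converged) {
    stop(sprintf("logistic fit did not converge in %d iterations (deviance %.6g)",
                 max_iter, fit$deviance))
  }
  beta <- fit$coefficients
  if (any(abs(beta[-1]) > 15) || (ncol(design) == 1L && abs(beta) > 15)) {
    stop("complete separation suspected: |coefficient| > 15")
  }
  w <- fit$weights
  xtwx <- crossprod(design * sqrt(w))
  cov <- solve(xtwx)
  se <- sqrt(diag(cov))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  or <- data.frame(
    estimate = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p = p)
  rownames(or) <- colnames(design)
  structure(
    list(coefficients = beta, covariance = cov, se = se, z = z, p = p,
         or = or, converged = fit$converged, n_iter = fit$iter),
    class = "ppsn_logit")
}

#' Two-group comparison with automatic test routing
#'
#' Mirrors the analysis plan for continuous variables: each group is
#' checked for normality (Shapiro-Wilk at `alpha`); if both pass, a
#' two-sided Student t-test (pooled variance) is used, otherwise a
#' Mann-Whitney U test with the tie-corrected normal approximation.
#' Groups smaller than 3 cannot be normality-checked and fall back to
#' Mann-Whitney with a warning.
#'
#' @param x,y numeric samples (missing values dropped).
#' @param alpha normality-test level (default 0.05).
#' @return List: `statistic`, `p`, `test_used` (`"t"` or
#'   `"mann_whitney"`), `normal_p` (the two Shapiro p-values, or NA).
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  small <- length(x) < 3L || length(y) < 3L
  if (small) {
    warning("group size < 3: normality not assessable, using Mann-Whitney")
    normal_p <- c(NA_real_, NA_real_)
    use_t <- FALSE
  } else {
    # shapiro.test requires non-degenerate input
    sw <- function(v) {
      if (stats::sd(v) == 0) return(0)
      stats::shapiro.test(v)$p.value
    }
    normal_p <- c(sw(x), sw(y))
    use_t <- all(normal_p > alpha)
  }
  if (use_t) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         test_used = "t", normal_p = normal_p)
  } else {
    if (stats::sd(c(x, y)) == 0) {
      # every observation tied: no evidence of any difference
      return(list(statistic = 0, p = 1, test_used = "mann_whitney",
                  normal_p = normal_p))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         test_used = "mann_whitney", normal_p = normal_p)
  }
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling; the two-sided p-value
#' uses the t approximation.  At least four complete pairs are required
#' and constant input is an error.
#'
#' @param x,y paired numeric vectors.
#' @return List: `rho`, `p`, `n`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("rank correlation needs >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for constant input")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
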