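#!/usr/bin/env Rscript
# Tumor-infiltrating lymphocyte analysis: compare CD3/CD8/CD56 TIL and
# sTIL counts between low and high PPSN classes, and correlate TILs with
# the peripheral pre-treatment lymphocyte count.

library(ppsn)

cohort <- read_cohort("results/cohort.csv")
report <- run_full_analysis(cohort)

if (is.null(report$tils)) {
  cat("no TIL data in the cohort; nothing to do\n")
  quit(status = 0)
}

cmp <- do.call(rbind, lapply(names(report$tils$comparisons), function(col) {
  x <- report$tils$comparisons[[col]]
  data.frame(til = col, statistic = x$statistic, p = x$p,
             test_used = x$test_used)
}))
write_report(cmp, "results/til_comparisons.tsv", format = "tsv")

cor_tab <- do.call(rbind, lapply(names(report$tils$correlations),
                                 function(col) {
  x <- report$tils$correlations[[col]]
  data.frame(til = col, rho = x$rho, p = x$p, n = x$n)
}))
write_report(cor_tab, "results/til_correlations.tsv", format = "tsv")

cat(sprintf("TIL data for %d patients\n", report$tils$n))
cat("low vs high PPSN comparisons:\n")
print(cmp, row.names = FALSE)
cat("correlation with peripheral pre-treatment lymphocyte count:\n")
print(cor_tab, row.names = FALSE)
cat("wrote results/til_comparisons.tsv and results/til_correlations.tsv\n")
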