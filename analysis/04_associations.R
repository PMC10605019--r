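#!/usr/bin/env Rscript
# Univariate odds ratios for mortality (each marker dichotomized at its
# derived cutoff, plus FIGO stage IV) and the two-predictor multivariate
# logistic model with the pre- and post-NACT lymphocyte counts.

library(ppsn)

cohort <- read_cohort("results/cohort.csv")
report <- run_full_analysis(cohort)

uni <- report$mortality$univariate
tab <- do.call(rbind, lapply(names(uni), function(v) {
  o <- uni[[v]]
  data.frame(variable = v, or = o$or_point, ci_low = o$ci_low,
             ci_high = o$ci_high, p = o$p,
             or_display = sprintf("%.2f (%.2f-%.2f)", truncate2(o$or_point),
                                  truncate2(o$ci_low), truncate2(o$ci_high)))
}))
write_report(tab, "results/mortality_univariate.tsv", format = "tsv")

multi <- report$mortality$multivariate
mt <- data.frame(term = rownames(multi$or), multi$or)
write_report(mt, "results/mortality_multivariate.tsv", format = "tsv")

cat("univariate mortality associations (OR, 95% CI):\n")
for (i in seq_len(nrow(tab))) {
  cat(sprintf("  %-28s %s  p = %.3g\n", tab$variable[i], tab$or_display[i],
              tab$p[i]))
}
cat("multivariate (pre + post lymphocyte counts):\n")
print(mt, row.names = FALSE)
cat("wrote results/mortality_univariate.tsv and results/mortality_multivariate.tsv\n")
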