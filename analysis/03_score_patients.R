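#!/usr/bin/env Rscript
# Score every patient on the 0-7 PPSN scale and derive the high/low
# threshold from the score's own ROC against mortality.

library(ppsn)

cohort <- read_cohort("results/cohort.csv")
cutoffs <- derive_panel_cutoffs(cohort)
scores <- ppsn_score(cohort, cutoffs)
thr <- derive_score_threshold(scores$score, cohort$death)
scores$class <- classify_ppsn(scores$score, thr)

write_report(scores, "results/ppsn_scores.tsv", format = "tsv")
write_report(list(threshold = thr$threshold, youden_j = thr$youden_j,
                  auc = thr$auc, auc_p = thr$auc_p),
             "results/ppsn_threshold.json", format = "json")

cat(sprintf("score distribution: %s\n",
            paste(names(table(scores$score)), table(scores$score),
                  sep = ":", collapse = " ")))
cat(sprintf("threshold: high PPSN is a score >= %d (J = %.3f, AUC = %.3f)\n",
            thr$threshold, thr$youden_j, thr$auc))
cat(sprintf("%d high / %d low\n", sum(scores$class == "high"),
            sum(scores$class == "low")))
cat("wrote results/ppsn_scores.tsv and results/ppsn_threshold.json\n")
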