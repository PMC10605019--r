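# ppsn

Prognostic scoring around neoadjuvant chemotherapy (NACT) for advanced
epithelial ovarian cancer.

Patients who cannot be debulked up front receive NACT followed by
interval debulking surgery, and their peripheral-blood inflammatory
profile — before treatment and again after chemotherapy — carries
prognostic information that single-timepoint indices miss.  The **PPSN**
(Prognosis Predictive Score around NACT) is a 0–7 count of abnormal
values among seven blood parameters:

| timepoint | parameter | abnormal when |
|---|---|---|
| pre-treatment | neutrophil % | ≥ cutoff |
| pre-treatment | lymphocyte % | ≤ cutoff |
| pre-treatment | lymphocyte count (×10²/µL) | ≤ cutoff |
| post-NACT | neutrophil % | ≥ cutoff |
| post-NACT | lymphocyte % | ≤ cutoff |
| post-NACT | lymphocyte count (×10²/µL) | ≤ cutoff |
| post-NACT | platelet count (×10⁴/µL) | ≤ cutoff |

Each cutoff is the value maximizing the Youden index J = Se + Sp − 1 on
the marker's ROC curve against mortality; scores ≥ 4 define the
high-PPSN (poor-prognosis) class.  The package implements the full
analysis pipeline: cohort CSV I/O and validation, ROC/Youden cutoff
derivation with AUC and Mann–Whitney p-values, diagnostic metrics
(Se/Sp/PPV/NPV), 2×2 odds ratios with Wald intervals, logistic
regression, Kaplan–Meier / log-rank survival at 3-year, 5-year and
unrestricted horizons, tumor-infiltrating-lymphocyte comparisons, a
calibrated synthetic-cohort generator (no patient-level data are
distributed), and a worked-example harness that reconstructs published
contingency tables from printed summary statistics.

## Worked example

```r
library(ppsn)

cohort  <- generate_cohort(paper_calibrated_config(seed = 1))
cutoffs <- derive_panel_cutoffs(cohort)          # Youden vs mortality
scores  <- ppsn_score(cohort, cutoffs)           # 0-7 per patient
thr     <- derive_score_threshold(scores$score, cohort$death)
lr      <- log_rank(cohort$os_days, cohort$death,
                    classify_ppsn(scores$score, thr))
```

Running the bundled drivers on this cohort (`Rscript
analysis/01_simulate_cohort.R` … `07_worked_examples.R`) prints, among
other things:

```
cohort: 72 patients, 47 deaths (65.3%), 5 lacking the pre-treatment panel
score distribution: 1:5 2:7 3:14 4:13 5:16 6:13 7:4
threshold: high PPSN is a score >= 5 (J = 0.641, AUC = 0.913)
 horizon                variable         or            p n_excluded
      3y               ppsn_high  8.7656250 6.138080e-04          2
      5y               ppsn_high 15.8181818 1.906568e-05          4
   total               ppsn_high 51.2000000 2.270635e-04          0
Worked-example checks: 60/60 pass
```

— i.e. on this synthetic realization the derived threshold is 5 (4 is
the modal value across seeds), high PPSN is strongly associated with
death at every horizon (odds ratios 8.8–51.2, with the count of
subjects excluded as unclassifiable at each horizon), and all 60
reconstructed published values are reproduced exactly.  Each script
writes its table under `results/` (`marker_cutoffs.tsv`,
`ppsn_scores.tsv`, `km_curves.tsv`, …).

The `analysis/` scripts form the narrative workflow: simulate a cohort,
derive cutoffs, score patients, run mortality associations, run
survival analyses, compare TIL counts, and re-derive the published
worked examples.

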