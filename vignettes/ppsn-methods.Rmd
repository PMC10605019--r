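---
title: "The PPSN composite score: model, cutoff derivation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PPSN composite score: model, cutoff derivation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppsn)
```

## The clinical problem

Advanced epithelial ovarian cancer that cannot be debulked up front is
treated with neoadjuvant chemotherapy (NACT) followed by interval
debulking surgery (IDS).  Peripheral-blood inflammatory markers — the
balance of neutrophils, lymphocytes and platelets — carry prognostic
information in this setting, but single-timepoint indices (NLR, PLR,
SII, GPS) ignore how the blood picture evolves through chemotherapy.
The PPSN (Prognosis Predictive Score around NACT) addresses this by
combining **both** timepoints: it counts abnormal values among seven
parameters,

* pre-treatment: neutrophil %, lymphocyte %, lymphocyte count
  (×10²/µL);
* post-NACT: neutrophil %, lymphocyte %, lymphocyte count (×10²/µL),
  platelet count (×10⁴/µL);

where *elevated* neutrophils and *decreased* lymphocytes and platelets
are abnormal.  A patient with every parameter abnormal scores 7; with
every parameter normal, 0.  Patients with a score of 4 or more form the
high-PPSN (poor-prognosis) class.

## Cutoff derivation

Each marker is dichotomized at the cutoff maximizing the Youden index
J = sensitivity + specificity − 1 on its ROC curve against overall
mortality.  The implementation makes three concrete choices the
procedure itself leaves open:

* **Candidate thresholds** are midpoints between consecutive distinct
  observed values, plus one sentinel below the minimum and one above the
  maximum.  Midpoints explain why derived cutoffs carry one more decimal
  than the underlying laboratory values (e.g. 14.15, 47.65, 17.35), and
  they guarantee no observed value falls on a threshold, so the choice
  of boundary side is observationally neutral.
* **The abnormal side is inclusive** (`value >= cutoff` when high is
  abnormal, `value <= cutoff` otherwise), matching the mixed ≥/≤
  labelling used when the dichotomized markers are tabulated.
* **Ties on J** are broken toward the threshold classifying fewer
  subjects as abnormal — the more specific rule.  Any rule would do;
  this one is deterministic and errs against overcalling abnormality.

The AUC is the trapezoid area, which — because thresholds sit strictly
between distinct values — equals the Mann–Whitney U statistic divided by
`n_pos * n_neg` with tied pairs counted ½.  The AUC p-value uses the
tie-corrected normal approximation of U.  The test suite holds both
identities to 10⁻¹² against brute-force pair enumeration and an
exhaustive threshold scan.

The score's own high/low threshold is derived by the *same* Youden
procedure applied to the integer score (the published analysis states
the threshold, 4, but not how it was chosen; re-deriving it mirrors the
marker procedure and is testable).  Because score thresholds are
midpoints like 3.5, the reported integer threshold t is the ceiling, so
"high" is `score >= t`.

## Missingness

Per-marker complete cases are used when deriving cutoffs, so
denominators legitimately differ between the pre-treatment markers and
the post-NACT markers when some patients lack a pre-treatment draw (in
the published cohort: 43 dead / 24 alive pre-treatment against 44 / 28
post-NACT; the reconstruction of those denominators is validated by the
worked-example harness, which reproduces every printed predictive value
from them exactly).  When *scoring*, a missing marker contributes 0 and
decrements `n_markers_available` rather than dropping the patient —
this keeps the full cohort in all score-level analyses, consistent with
the published analysis retaining n = 72.  `ppsn_score()` reports
`n_markers_available` so users preferring complete-case scoring can
filter on it.

## Association and survival analyses

Dichotomized markers are related to mortality by cross-product odds
ratios with 95% Wald intervals, exp(ln OR ± 1.96·SE),
SE = √(1/a + 1/b + 1/c + 1/d).  The published univariate table labels
these "risk ratios", but every printed value matches the cross-product
odds ratio of the reconstructed counts, so odds ratios they are.  The
Haldane–Anscombe 0.5 correction is applied only when a cell is zero;
printed values imply no correction on non-zero tables.  Logistic models
are fitted by IRLS (through `stats::glm.fit`) with Wald z-tests; for a
single binary predictor, exp(slope) reproduces the cross-product OR to
10⁻⁶, an identity the acceptance suite checks on random tables.
Multivariate models fit exactly the predictors the caller lists — the
published variable-selection rule is undocumented, so no stepwise
machinery is offered.

Group comparisons of continuous variables follow the published plan:
Shapiro–Wilk on each group at α = 0.05; Student t (pooled variance) if
both pass, otherwise Mann–Whitney with the tie-corrected normal
approximation.  TIL–lymphocyte correlations use Spearman's rank
correlation (the published method is unnamed; ranks are the conservative
choice for count data).

Survival uses the Kaplan–Meier product-limit estimator and the
unweighted log-rank test (`survival::survfit`/`survdiff` behind the
package's interfaces), with events preceding censorings at tied times.
Horizon-restricted analyses (3-year = 1095 d, 5-year = 1825 d, total =
unrestricted) come in two forms:

* **Curves/log-rank**: follow-up beyond the horizon is administratively
  censored at the horizon.
* **Binary endpoints** for logistic analyses: event within the horizon →
  positive; followed beyond it event-free → negative; censored event-free
  *before* the horizon → excluded, with the exclusion count reported so
  the analysis can be audited.  The published analysis is silent on this
  point; exclusion is the only classification-free option.

The PFS event is recurrence or death, whichever comes first, and the
time origin is the start of NACT.  Marker cutoffs are derived once
against mortality and reused for PFS, as in the published analysis.

## The synthetic-cohort generator

No patient-level data are distributed, so the package ships a generator
(`generate_cohort()`) whose default configuration
(`paper_calibrated_config()`) emulates the study conditions: n = 72,
mortality 61.1%, per-marker discrimination in the AUC ≈ 0.65–0.70 band,
correlated pre/post marker panels, Weibull survival, and TIL counts for
a third of the cohort.

The generative model is two-stage:

1. Each patient receives seven latent **abnormality indicators** from a
   Gaussian copula.  Marginal abnormal prevalences are the test-positive
   fractions of the reconstructed published contingency tables (0.49,
   0.31, 0.39 pre; 0.50, 0.61, 0.75, 0.43 post); pre/post pairs of the
   same marker correlate at 0.5 and all other pairs at 0.25, reflecting
   that inflammatory abnormalities co-occur.
2. Death is Bernoulli with log-odds **linear in the abnormality count**
   S: logit P(death) = β₀ + β·S with β = `latent_effect`; β₀ is solved
   so the cohort-mean death probability equals the mortality target.
   Because death depends on the markers only through S, a logistic fit
   of death on the true S is correctly specified, which makes
   "latent-effect recovery" a well-posed assertion: its Wald 95% CI
   covers the generative β at the nominal rate (the acceptance suite
   measures 93–97% over 500 cohorts).

Marker values are then drawn on the side of the marker's true cutoff
that its indicator dictates — half-normal spreads away from the cutoff,
on the log scale for counts (guaranteeing positivity) and the percent
scale for proportions, with pairwise rejection-resampling (never
truncation, which would pile mass on the boundary) to keep
neutrophil % + lymphocyte % ≤ 100.  Side-conditional drawing makes the
true cutoff exactly recoverable: in a separable configuration
(indicators nearly perfectly correlated, overwhelming latent effect,
prevalences and mortality matched at 0.5) the derived Youden cutoff
falls within one inter-observation gap of the generative truth in ≈95%
of marker × replicate cases.

`latent_effect = 1.1` is the shipped default: under it the simulated
mean mortality sits at ≈0.61, the modal derived score threshold over
repeated cohorts is 4, and mean per-marker AUCs span ≈0.65–0.70 — the
three distributional targets the default configuration is defined by.
Survival defaults (Weibull shape 1.4, scale 1105 d for deaths, so median
time to death ≈ 850 d; survivor follow-up uniform on 900–5110 d; mean
PFS/OS fraction 0.65) give realistic event spacing across all three
horizons, including a small number of horizon exclusions.

What the generator does **not** emulate: longitudinal chemotherapy-cycle
dynamics (pre and post panels are drawn jointly, not mechanistically),
per-histology marker distributions, and any real measurement error
structure.  Passing tests therefore demonstrate that the *pipeline*
recovers what this class of data-generating process encodes — not that
the published effect sizes would replicate in new patients.

```{r example}
cohort <- generate_cohort(paper_calibrated_config(seed = 1))
cutoffs <- derive_panel_cutoffs(cohort)
scores <- ppsn_score(cohort, cutoffs)
derive_score_threshold(scores$score, cohort$death)$threshold
```

## Numerical and display conventions

* Percentages (PPV, NPV) and odds ratios are displayed **truncated** —
  not rounded — to two decimals (`truncate2()`): 27/33 prints as 81.81,
  not 81.82.  This is purely a display convention, inferred from the
  published tables, and is never used in computation; every display
  value has a full-precision twin.
* Sensitivity and specificity are displayed rounded to 3 decimals.
* Serialization (`write_cohort()`, `write_report()`) uses 17 significant
  digits, so write-then-read round-trips doubles exactly and repeated
  writes are byte-identical.
* Degenerate inputs fail loudly: single-class outcomes, constant
  scores, all-missing marker panels and diagonal-zero 2×2 tables raise
  errors; an all-tied marker yields the AUC-0.5 degenerate curve with a
  warning; undefined predictive values (empty margin) are reported
  missing with a warning.

## Problem sizes

The simulation-based checks use cohorts of n = 72 (the study size):
500 replicates for mortality calibration and latent-effect coverage,
200 for the modal score threshold, the AUC calibration and separable
cutoff recovery, and 1000 random small instances for each ROC oracle
identity.  These sizes keep Monte-Carlo error comfortably inside the
asserted bands while the whole suite runs in about a minute.

## Known limitations

* The score threshold is re-derived per cohort; on a single synthetic
  realization it can come out 3 or 5 (4 is the modal value), so analyses
  of one cohort should report their realized threshold, as
  `run_full_analysis()` does.
* No DeLong CI for AUC, no Cox regression, no competing risks, no exact
  (Fisher) intervals: the package reproduces the published analysis
  plan, which used none of these.
* Horizon-binary logistic analyses on 72 patients can meet complete
  separation (e.g. every early death in the high-PPSN class);
  `run_full_analysis()` records the failure for that block instead of
  inventing a finite estimate, and the 2×2 odds ratio with the
  Haldane–Anscombe correction remains available.
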