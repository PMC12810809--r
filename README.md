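# doifusion

Statistical pipeline for preoperative **depth of invasion (DOI)** analysis
in tongue squamous cell carcinoma. DOI — the distance from the
reconstructed normal-mucosa basement plane to the deepest tumor point — is
the key preoperative predictor of cervical lymph-node metastasis (CLNM),
but the two preoperative modalities err differently: ultrasound (usDOI) is
accurate for shallow tumors and drifts toward underestimation beyond about
10 mm, while MRI (mrDOI) overestimates at all depths but retains the depth
signal for deep infiltration. `doifusion` implements, end to end:

* **Agreement with pathology** — Pearson correlation, simple linear
  regression and Bland–Altman analysis (bias, SD of differences, 95%
  limits of agreement `bias ± 1.96·SD`, differences oriented imaging −
  pathology) plus a proportional-bias test (OLS of differences on
  pairwise means).
* **ROC prediction of CLNM** — ROC curves, AUC computed both as the
  Mann–Whitney probability `P(score_pos > score_neg) + ½·P(tie)` and as
  the trapezoidal area (asserted equal to 1e−12), and Youden-optimal
  cutoffs with midpoint placement between observed scores.
* **Composite us/mrDOI biomarker** — the switching rule
  `us/mrDOI = usDOI if usDOI ≤ t, else mrDOI`, with the threshold `t`
  selected by a grid search over the deciles of the complete-case usDOI
  distribution, each candidate scored by the AUC of a univariable
  logistic model of CLNM on the composite.
* **Synthetic cohorts** — a calibrated generator with a piecewise-linear
  ultrasound error model (knot at 10 mm), depth-dependent ultrasound
  availability and logistic CLNM, plus a Gaussian-copula variant that
  targets imaging–pathology correlations directly; both fully seeded and
  reproducible, so every stage is testable without patient data.

## Worked example

```r
library(doifusion)

# a 46-patient synthetic cohort under the default calibration
rep <- run_full_analysis(analysis_config(seed = 2026))
print(rep)
```

```
DOI analysis report
  Subsets: total 46 | US 21 | MRI 46 | complete 21
  usDOI vs pDOI: r = 0.918, bias +0.72 mm, LoA [-3.65, 5.09]
  mrDOI vs pDOI: r = 0.980, bias +2.24 mm, LoA [-3.41, 7.90]
  ROC usDOI:    AUC = 0.911, cutoff = 6.68 mm
  ROC mrDOI:    AUC = 0.694, cutoff = 13.98 mm
  ROC pDOI:     AUC = 0.781, cutoff = 13.23 mm
  ROC us/mrDOI: AUC = 0.911, cutoff = 6.68 mm
  Grid search: best threshold 11.98 mm (AUC 0.911, n = 21)
```

Reading the report: of 46 simulated patients, 21 had an ultrasound DOI
(US is preferentially performed for shallow tumors), 46 an MRI DOI and 21
complete triplets. Ultrasound agrees with pathology with a small bias
(+0.72 mm) while MRI overestimates by +2.24 mm, matching the calibrated
error models. Each ROC line gives the AUC for predicting CLNM from that
score on its own availability subset — they are **not** directly
comparable across subsets — and the grid search reports the switching
threshold whose composite maximizes the AUC among the complete cases. At
n = 46 these quantities are intentionally noisy; the calibration-recovery
checks at n = 20,000 live in the test suite.

Individual stages are plain functions:

```r
co <- generate_cohort(generator_params(seed = 1))
ba <- bland_altman(co$us_doi_mm[!is.na(co$us_doi_mm)],
                   co$p_doi_mm[!is.na(co$us_doi_mm)])
roc <- roc_report(co$p_doi_mm, co$clnm)
gs  <- grid_search(co)
```

A thin command-line wrapper with verbs `simulate`, `analyze`,
`gridsearch` and `fixtures` is installed at
`system.file("scripts", "doi-pipeline.R", package = "doifusion")`.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic cohorts | `generator_params`, `generate_cohort`, `generate_copula_cohort`, `regime_shift_params`, `summarize_cohort` |
| Agreement | `pearson_with_test`, `linear_fit`, `bland_altman`, `proportional_bias_test`, `plot_bland_altman` |
| ROC | `roc_curve`, `auc`, `auc_trapezoid`, `youden_cutoff`, `roc_report` |
| Fusion | `compose_doi`, `candidate_thresholds`, `fit_logistic`, `grid_search` |
| Pipeline & I/O | `analysis_config`, `run_full_analysis`, `read_cohort_csv`, `write_cohort_csv`, `make_fixtures`, `report_to_json` |

The methods vignette (`vignettes/composite-doi-methods.Rmd`) documents the
models, calibration choices, numerical conventions and known limitations.
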