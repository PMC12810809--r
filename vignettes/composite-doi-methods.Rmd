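---
title: "Methods: agreement, ROC and switching-threshold fusion for preoperative DOI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement, ROC and switching-threshold fusion for preoperative DOI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doifusion)
```

## The problem

Depth of invasion (DOI) — the perpendicular distance from a reconstructed
normal-mucosa basement plane to the deepest tumor cell — is the strongest
preoperative predictor of cervical lymph-node metastasis (CLNM) in tongue
squamous cell carcinoma, and drives the decision for elective neck
dissection. Pathological DOI (pDOI) is only known after surgery; the
preoperative estimates come from ultrasound (usDOI) and MRI (mrDOI), and
the two modalities fail differently. Ultrasound is precise for shallow
tumors but loses the deep margin as depth grows; MRI visualizes deep
infiltration but overestimates depth at all levels, largely from
peritumoral inflammation. This package implements the statistical pipeline
for studying that complementarity: agreement of each modality with
pathology, ROC prediction of CLNM, and a *composite* biomarker (us/mrDOI)
that uses the ultrasound reading up to a switching threshold and the MRI
reading above it, with the threshold selected by a grid search over usDOI
percentiles.

## Agreement statistics

`bland_altman()` orients every difference as **imaging minus pathology**,
so a positive bias means overestimation; the convention matters because
the sign carries the clinical message (underestimation risks
undertreatment). The limits of agreement are `bias ± 1.96 × SD` of the
differences, with the sample SD (denominator `n − 1`). The 1.96 multiplier
is fixed rather than a small-sample *t* quantile: it is the convention of
the agreement literature, and every recovery target in this package is
evaluated at Monte-Carlo sample sizes where the distinction is
irrelevant.

Depth-dependent ("proportional") bias is assessed by OLS of the
differences on the pairwise means (`proportional_bias_test()`), the
standard Bland–Altman extension; a changepoint estimator was deliberately
not used, because the regime-change depth is a *generator* concept and an
estimator should not presuppose it. One property of this regression is
worth knowing: when the reference is essentially noise-free (pathology)
and the measure carries error with variance σ², the slope's expectation
under a truly depth-independent bias is not 0 but σ²/(2·var(mean)) — a
regression-to-the-mean artifact. It is negligible whenever the depth
variance dominates the measurement-error variance, which holds for every
configuration used in the tests, but the test for the null case keeps the
artifact an order of magnitude below the detection limit by construction
rather than pretending it does not exist.

## ROC analysis

`roc_curve()` builds one point per distinct threshold of the decision
rule *score ≥ t → positive*, ties sharing a point, anchored at (0, 0).
The AUC is computed by two genuinely independent routes that are asserted
equal to 10⁻¹²: the trapezoidal area under the curve (`auc_trapezoid()`)
and the Mann–Whitney probability from midranks (`auc()`), with tied pairs
credited 0.5. Ties are not an edge case here — DOI is read at 0.1 mm
resolution — hence the explicit half-credit convention.

The optimal cutoff maximizes Youden's J (sensitivity + specificity − 1).
No selection criterion is canonical, but Youden is the near-universal
default of clinical ROC reporting, so it is the default here, with the
closest-to-(0, 1) criterion available behind a flag. Two conventions are
made explicit because they silently differ between packages:

* **Tie-break:** equal J goes to the *higher* threshold (fewer
  test-positives).
* **Cutoff placement:** the reported cutoff is the midpoint between the
  selected observed score and the next lower distinct score when one
  exists. This matches common statistical-package behavior and explains
  why reported cutoffs (e.g. 9.5 mm) need not be observed values.

No AUC confidence intervals or DeLong comparisons are produced: the
analyses this package mirrors report point estimates only, and adding
inferential machinery the data cannot support would suggest otherwise.

## The composite biomarker and the grid search

`compose_doi(us, mr, t)` returns usDOI when usDOI ≤ t and mrDOI when
usDOI > t — strict inequality, so a reading exactly at the threshold stays
with ultrasound. Candidate thresholds are the 10th–90th percentiles of
the complete-case usDOI sample (nine candidates on continuous data). The
percentile definition defaults to linear interpolation between order
statistics (`stats::quantile` type 7) and is configurable: printed
threshold grids in the literature cannot adjudicate the convention
without the raw sample, so it is a parameter, not a guess.

For each candidate, `grid_search()` forms the composite, fits a
univariable logistic model of CLNM on it, and evaluates the AUC **of the
composite score directly**. Because AUC is invariant to the monotone
logit, this equals the AUC of the fitted probabilities whenever the
fitted slope is positive — an identity asserted on every grid cell — while
removing IRLS convergence fragility from the selection criterion itself;
the logistic coefficients are retained in the result, and a non-positive
slope at the selected threshold raises a warning rather than silently
diverging from the fitted-probability route. Ties in the maximum AUC go
to the *smallest* threshold, which keeps more patients on the
better-validated shallow-ultrasound regime. Only complete cases (usDOI,
mrDOI, pDOI, CLNM all present) enter; no imputation is performed.

Two degeneracy identities pin the grid's endpoints: a threshold above
`max(usDOI)` reproduces the usDOI-only AUC exactly, one below
`min(usDOI)` the mrDOI-only AUC (on the same complete-case subset). These
are tested as exact equalities.

A known limitation, inherited deliberately: the selected threshold is not
optimism-corrected (no cross-validation or bootstrap), so the best AUC is
an in-sample quantity. The package mirrors the exploratory design it
implements; a validation layer would be the natural extension.

## The synthetic cohort generator

No patient-level data are distributable, so `generate_cohort()` emulates
the *statistical structure* of a 46-patient cohort. Its defaults are the
study conditions, chosen once:

* **Depth marginal** — lognormal, median 8 mm, `sdlog` 0.95 (quartiles
  ≈ 4.2 / 15.2 mm). No depth distribution is published for this setting;
  this marginal was chosen so that the usDOI deciles bracket the
  4.1–14.8 mm range over which switching thresholds are plausibly
  searched, and it is the one genuinely invented default.
* **Ultrasound error** — piecewise-linear bias with a single knot:
  +0.88 mm (SD 1.59 mm) up to 10 mm, plus `us_bias_deep_slope`
  (default −0.5) per mm beyond it. The knot-with-slope form is the
  simplest model that reproduces the observed Bland–Altman pattern
  (accurate shallow, progressively underestimating deep); the published
  evidence for the 10 mm regime change is visual, so the knot is a
  generator parameter, never an estimator output.
* **MRI error** — depth-independent +2.43 mm bias, SD 2.39 mm.
* **CLNM** — logistic in pDOI with β₀ = −1.39, β₁ = 0.10/mm, calibrated
  by simulation (2×10⁵ draws) to give 43.5% prevalence (the study's
  20/46) under the default marginal; the implied pDOI AUC is ≈ 0.73,
  consistent with the modest discrimination reported in this setting.
* **Availability** — ultrasound availability is logistic in pDOI with a
  negative slope (β₀ = 2.50, β₁ = −0.25), calibrated to the 24/46
  marginal: US is preferentially performed for tumors presumed shallow,
  which is why observed usDOI samples are depth-biased. MRI is missing
  completely at random at 2/46.

Negative imaging draws are truncated at 0 rather than resampled: the
generator stays a pure transform of one noise draw per field, which keeps
seeds reproducible field-by-field, at the cost of a slight upward bias at
tiny depths (quantified in the tests as negligible at the default
marginal). Seeding uses one root seed from which five sub-streams (pDOI,
US noise, MRI noise, CLNM, missingness — in that fixed order) are
derived, so adding a downstream field can never perturb earlier draws.

`generate_copula_cohort()` is the complementary generator: instead of an
error model it targets *correlations* directly through a Gaussian copula
(latent correlations `r_us`, `r_mr`; the us–mr entry imputed as their
product by default, which is always positive semidefinite). With normal
marginals the latent correlation is exactly the output Pearson
correlation, which is what makes it the right instrument for
correlation-recovery checks at r ≈ 0.956/0.958.

### The regime-shift stress scenario

`regime_shift_params()` encodes the scenario for threshold-recovery
studies: US SD 0.6 mm shallow, deep slope −0.95 (the reading keeps only
0.05 mm of signal per mm of true depth beyond 10 mm), MRI SD 3.0 mm, CLNM
slope 0.25/mm, full availability, n = 200. Two modelling points deserve
emphasis:

* "Strong deep-regime degradation" must mean **attenuation**, not
  inversion. With a slope below −1 the deep ultrasound reading *decreases*
  with true depth, so the deepest tumors present low usDOI — and a switch
  rule triggered by *high* usDOI structurally cannot identify them. The
  composite can only repair a deep regime whose readings still clear the
  threshold. At −0.95 the deep signal is nearly flat but not inverted,
  which is also what the published Bland–Altman pattern shows.
* The CLNM slope is steeper than the default because at n = 200 the AUC
  differences between neighbouring thresholds must exceed Monte-Carlo
  noise for the argmax to be identifiable at all; with the default 0.10/mm
  the AUC profile is too flat for any method to localize the knot.

Under this scenario the median selected threshold across 100 replicates
falls within one decile step of the 10 mm knot and the composite's AUC
beats both single-modality AUCs in well over 80% of replicates — both
checked in the test suite.

## What the synthetic cohorts do and do not establish

Passing recovery tests shows the *estimators* are correct and the
*pipeline* is faithful to its contracts under a data-generating process
with: independent Gaussian measurement errors, a single sharp knot,
logistic outcome and availability models, and modality availability
independent given depth. Real cohorts violate most of these —
formalin-fixation shrinkage couples the errors to pathology, observer
effects correlate usDOI and mrDOI errors, availability depends on
clinician judgment not captured by depth alone, and the 22-patient
complete-case subset of a 46-patient study carries selection effects the
independence assumption cannot represent. The tests validate the
machinery, not the clinical conclusions; headline estimates from any
46-patient cohort remain exploratory regardless of how well the software
reproduces them.

## Problem sizes and numerical conventions

Monte-Carlo recovery checks use n = 20,000 (bias and SD recovered within
3 standard errors; correlations within 0.01); property-based suites use
200 random fixtures of n ≤ 50; threshold recovery uses 100 replicates of
n = 200. These sizes put every stochastic assertion at least 3 SEs from
its boundary while keeping the full suite in seconds. Logistic fits use
`stats::glm` (binomial IRLS, tolerance 10⁻¹⁰, 100 iterations); complete
separation — in the univariable case exactly non-overlapping class
ranges — is detected directly and reported as a non-converged fit with
the last iterate, since the MLE is then at infinity. All JSON output
carries full-precision values plus a rounded block (mm to 2 decimals,
AUC to 3) for rendering.
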