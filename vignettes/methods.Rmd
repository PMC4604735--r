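---
title: "Methods: severity scoring and validation for ICU cirrhosis cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity scoring and validation for ICU cirrhosis cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpl)
```

## The problem and the score

Critically ill patients with cirrhosis are poorly served by the general ICU
severity scores (APACHE II, SOFA) and by the classic liver scores (CTP,
MELD, UKELD): in general-ICU cohorts these often fail the conventional
clinical-usefulness bar of ROC AUC ≥ 0.8 for predicting ICU mortality.
Admission arterial lactate is a strong independent mortality signal in this
population, and the CTP+L score exploits it in the simplest possible way:
the banded Child-Turcotte-Pugh sum (five components, 1–3 points each, total
5–15) plus the *raw* lactate concentration in mmol/L. The package's job is
to compute this score and its comparators correctly, and to run the
validation machinery — univariate association, ROC/Youden/DeLong analysis,
logistic model selection, cross-cohort transport — that a validation study
of such a score requires.

## Score engine

**CTP band closure.** The published band table leaves hairline gaps at the
component boundaries (e.g. INR bands printed as "<1.7", "1.71–2.30",
">2.3"). We close them as: bilirubin band 2 = [34, 50] µmol/L; albumin
band 2 = [28, 35] g/L; INR band 1 = (−∞, 1.70], band 2 = (1.70, 2.30].
The bands are then exhaustive and every in-domain value scores. PT ratio is
used interchangeably with INR.

**Encephalopathy modes.** Pre-intubation West Haven grades are often not
collectable. `compute_ctp()` supports `observed` (use the recorded grade),
`presumed_2` (award 2 points regardless — the convention for cohorts
without pre-intubation grades; in `compute_panel()` this also feeds grade 2
to any definition that scores encephalopathy, such as CLIF-SOFA), and
`excluded` (four-component sum, range 4–12). The pipeline compares
`observed` vs `excluded` CTP/CTP+L curves with the paired DeLong test.

**Configurable definitions.** MELD, UKELD, SOFA, CLIF-SOFA, APACHE II and
RFH ship as YAML documents validated structurally (strictly increasing
edges, one more point value than edges, integer non-negative points, known
fields). Two kinds exist: `band_sum` (left-closed right-open bands over
ascending lower-bound edges, plus an optional constant offset) and
`linear_predictor` (intercept + coefficient × identity- or log-transformed
value, with per-component floor/cap clamps applied before the transform —
e.g. MELD's floor of 1.0 on all log inputs and 4.0 mg/dL creatinine cap).
Unit conversions are carried by derived fields: kPa → mmHg (×7.50062),
bilirubin µmol/L → mg/dL (÷17.1), creatinine µmol/L → mg/dL (÷88.4).

Two definitions are deliberately approximate and say so in their files:

* **APACHE II** uses first-available admission values, not worst-in-24-h,
  and covers only the physiology variables in the collected set;
  temperature, heart rate, respiratory rate, arterial pH and haematocrit
  are absent and the present components score their zero-point band when
  missing ("normal-if-missing"). Computed APACHE II values therefore sit
  below full-chart values and its discrimination in emulated cohorts is
  weak; this is a property of the restricted input set, not a bug.
* **RFH** is *provisional*: the primary-source coefficients were not
  available when the definition was transcribed. The shipped file keeps
  the published input set (log bilirubin, log lactate, PT ratio, urea,
  organ-failure count over six configurable criteria) with synthetic
  coefficients scaled to the published score distribution's magnitude
  (median near 0, IQR roughly −1 to 2).

## Univariate battery

Welch *t* (unequal variances, Satterthwaite df) for variables presented as
mean (range); Mann-Whitney *U* with midrank ties for variables presented as
median (IQR) — exact enumeration when both groups have fewer than 8 values
and no ties, otherwise the continuity-corrected normal approximation; and
for categorical variables, Yates-corrected chi-squared, replaced by
Fisher's exact test (two-sided probability-mass convention) whenever any
expected cell count is below 5. "Any expected count < 5" is our
operationalisation of "where appropriate"; the convention is recorded in
the output (`test` column). The variable plan is configurable per field
because published tables imply the parametric/non-parametric choice per
variable; the default follows the mean-vs-median presentation. Summaries
use quantile type 7 (linear interpolation between closest ranks) — the
quantile convention is not stated in the sources, so we fix and document
one. Percentages use the full cohort denominator, including records
missing other fields. Continuity-corrected categorical tests are
conservative by construction: their actual size at moderate cell counts is
2–4% at nominal 5%, which is why the suite checks a one-sided size bound
for them and a two-sided band only for Welch and Mann-Whitney.

## ROC analysis

The empirical ROC is built over all distinct score values, predicting
death when the score exceeds the threshold. The AUC is computed by two
independent routes — trapezoidal integration of the curve and the midrank
Mann-Whitney formula (ties counted one half) — and the implementation
refuses to return if they disagree beyond 1e-12. DeLong variance comes
from the sample variances (and, for the paired test, covariances) of the
per-subject placement values; intervals are Wald on the AUC scale,
truncated to [0, 1], with a zero-width interval and a warning at AUC
exactly 0 or 1. Identical paired curves give z = 0 exactly.

Youden cut points search the midpoints between consecutive distinct
observed scores — for integer-valued scores this yields the half-integer
cut points familiar from published ROC tables. Degenerate all-positive /
all-negative thresholds are *not* candidates, so an anti-informative score
can have a negative maximal J; ties are broken toward higher specificity,
then the lower threshold. Scores where low values indicate death use an
orientation flag rather than sign-flipped data. The AUC ≥ 0.8
clinical-usefulness rule is exposed as `clinically_useful()`.

## Logistic modelling

`fit_logistic()` is maximum likelihood via iteratively reweighted least
squares (convergence 1e-8, 100 iterations), requiring ≥ 10 complete cases
and both outcome classes. Rank deficiency (aliased columns) and
(quasi-)perfect separation — diverging scale-adjusted slopes, a vanishing
deviance, or extreme fitted probabilities — raise errors naming the
culprit predictor. Odds-ratio CIs are Wald (`exp(coef ± 1.96·SE)`);
published CIs of this kind look symmetric on the log scale, and the choice
is recorded here rather than configurable.

Stepwise selection is greedy and bidirectional from the intercept-only
model, scanning candidates in declared order, taking the lowest-AIC move
only if it strictly improves, breaking ties toward fewer parameters. The
record set is fixed to complete cases over *all* candidates before the
search (mirroring the study's exclusion of incomplete records before model
selection), so every model in the path is fitted to the same data and AICs
are comparable; selection is invariant to record order. Note the
statistical behaviour of AIC selection: a pure-noise candidate enters with
probability ≈ P(χ²₁ > 2) ≈ 0.16, so with several noise candidates the
selected model usually carries one or two of them alongside the real
signal; what is reliable is that informative predictors are retained.

Cross-cohort transport takes a fitted model, finds the Youden cut of its
linear predictor on the source cohort, predicts death in the target when
the linear predictor exceeds that cut, and scores the predicted-by-observed
2×2 table with Yates chi-squared and the phi coefficient
`(ad − bc)/√((a+b)(c+d)(a+c)(b+d))`; a degenerate margin yields a missing
phi with a warning. The lactate odds ratio is per 1 mmol/L and the PT-ratio
odds ratio per 1.0 increase of the ratio.

## Synthetic cohorts

The generator emulates the *published summary structure* of the two study
cohorts, not their joint distribution:

* Right-skewed labs (urea, lactate, creatinine, bilirubin, PT ratio, PaO2,
  noradrenaline dose) are lognormal, calibrated so `exp(µ)` equals the
  published median and σ minimises the squared relative error of the two
  quartiles (`calibrate_lognormal()`; exact when the quartiles are
  log-symmetric, least-squares otherwise, residual reported). Roughly
  symmetric variables (age, sodium, potassium, WCC, albumin) are truncated
  normal with the published mean and a range-implied sd. Categorical
  variables (sex, aetiology, ascites, encephalopathy, GCS) use the
  published prevalences; encephalopathy's 34.5% any-grade rate is split
  uniformly over grades 1–4 because no grade breakdown is published.
  Truncation bounds are physiologic (e.g. lactate 0.3–25 mmol/L), drawn by
  inverse-CDF so no rejection loop is needed; the PaO2/FiO2 ratio is
  clamped to at most PaO2/0.21 so the implied FiO2 stays in [0.21, 1].
  Noradrenaline mixes a point mass at zero (no vasopressor) with a
  lognormal dose.
* ICU death is Bernoulli with logit linear in lactate, bilirubin, PT ratio
  (positive) and PaO2/FiO2 ratio (negative), evaluated on pre-missingness
  values. Coefficient sizes are fixed by a design requirement: at the
  study's cohort sizes (84 and 115) the univariate battery must flag all
  four predictors at α = 0.05 in at least 80% of replicates. Published
  odds-ratio magnitudes are too small to meet that at n = 84, so the
  shipped coefficients are larger — Glasgow (1.8, 0.028, 3.5, −0.18) and
  London (1.3, 0.030, 3.5, −0.24) per (lactate mmol/L, bilirubin µmol/L,
  PT ratio, PaO2/FiO2 kPa). The intercept is then bisection-calibrated
  (`calibrate_intercept()`, one fixed-seed 100 000-draw covariate sample,
  tolerance 0.0005) to the published marginal mortality: 30% Glasgow, 37%
  London.
* Missingness is independent per variable; rates on the four model
  predictors (1.5% each Glasgow, 0.2% London) reproduce the published
  complete-case exclusion magnitudes (about 5 of 84 and 1 of 115).
* The London configuration carries no encephalopathy grades (they were not
  collected pre-intubation in that cohort); the pipeline scores it with
  `presumed_2`.

**What the emulation does not capture.** Variables are independent given
the outcome model — no bilirubin–PT-ratio or lactate–creatinine
correlation, because no correlation structure is published. Consequently
composite scores that pool many correlated organ systems behave somewhat
differently than on real data, and because the provisional RFH definition
shares its inputs with the synthetic outcome model, RFH dominates the
emulated ROC comparisons by construction — the combined-cohort CTP+L vs
RFH comparison is reported but its outcome is an artifact of the
emulation, not evidence about the real scores. Passing tests on these
cohorts demonstrates correctness of the machinery and calibration of the
generator, not clinical performance.

## Numerical and testing choices

* Missing data are a single explicit `NA`; nothing is imputed at read time
  and blank cells round-trip as blanks.
* All randomness flows through a single integer seed; identical seeds give
  bit-identical cohorts and byte-identical report bundles (no timestamps
  in any output). Seeds stay below 2³¹.
* Report bundles are written to a temporary directory and copied into
  place only on success, so a failed stage leaves no partial outputs.
* Problem sizes in the test suite are chosen to keep the full run under a
  minute while leaving Monte-Carlo margins honest: type-I-error checks use
  2000 replicates (±1.5% band around 5% covers the ~0.5% MC error), the
  DeLong-vs-bootstrap calibration uses 2000 resamples at n = 200 (15%
  tolerance), stepwise consistency uses 100 replicates at n = 300, and
  generator calibration is checked at n = 50 000–100 000.
* The ROC/DeLong implementation is cross-checked in the tests against an
  independent implementation (pROC) to 1e-10 on AUC, CI and paired-test
  p; the cross-check never substitutes for the package's own computation.

## Limitations

The RFH coefficients are provisional (above); APACHE II is structurally
restricted to the collected variable set; the banded-lactate CTP variant
is not implemented because its lactate band edges are not published; no
multiplicity correction is applied to univariate p-values (the study
design reports unadjusted values); and hospital (post-ICU) mortality is
carried as an optional field but not modelled.
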