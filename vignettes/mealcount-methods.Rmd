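---
title: "Models and methods behind mealcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mealcount}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealcount)
```

## The problem

Hospitalized patients — particularly older, severely ill ones — frequently
maintain energy intakes too low to prevent new nutritional deficits, and the
care team often does not notice. Precise calorie counts are the remedy, but
the traditional workflow (a hand-written listing of every item on the tray,
followed by a manual database lookup for each food) is so labor intensive
that in practice staff substitute rough categorical guesses.

`mealcount` implements the accounting and evaluation machinery for a
multi-component alternative: a pre-generated per-tray checklist (the NIAF),
bedside observation on a continuous percent-consumed scale, and before/after
photographs used for verification and ongoing quality control. The package
covers three layers:

1. the *intake engine* that turns menu cycles, food-composition data, and
   recorded percentages into served/consumed nutrient totals;
2. the *quality-control rules* used with photograph review;
3. the *evaluation statistics* by which such a system is judged — agreement
   with weighed reference values, inter-rater reliability, and time
   efficiency — plus a simulator that reproduces the evaluation designs so
   every statistic can be exercised without access to ward data.

## Intake accounting

The reference measurement of consumption is gravimetric:

$$\text{pct} = \frac{\text{original weight} - \text{leftover weight}}
{\text{original weight}} \times 100 .$$

Raters record percent consumed per item on a continuous 0–100 scale rounded
to the nearest integer; the continuous scale avoids the systematic error of
the traditional categorical quarters (0/25/50/75/100). Fractional inputs
are rejected rather than silently rounded, so the stored value is always
exactly what the rater entered — safer for audit. Consumed nutrients per
line are `profile × servings × pct/100`; meal totals are line sums; day
totals are meal sums. Nutrient densities are per serving *as served*;
weighed workflows additionally require `serving_weight_g` in the food
database so energy can be expressed per gram.

Internally totals use double-precision arithmetic (inputs are integer
percentages and small serving fractions, so the bilinear identities —
linearity in pct, additivity across meals, consumed ≤ served — hold to
machine precision); printed reports round to 0.1 kcal. Mid-meal additions
count as served (they reached the patient). Outside foods are registered in
the food database with a complete profile and remain available for reuse.

## Quality control

A second rater periodically re-estimates consumption from the photographs.
The two thresholds are read literally from their operating rule:

* an item is flagged when the absolute discrepancy is **strictly greater**
  than the item threshold (default 15 percentage points); a difference of
  exactly 15 is not an error signal;
* retraining is indicated when the potential-error rate **reaches**
  (≥) the rate threshold (default 5%).

When bedside and photo estimates disagree, the bedside (direct observation)
value wins unless the reviewer identified an obvious error such as a typo
(100 entered for 10) or an omitted item. Whether the 5% trigger should pool
across reviewers is not specified anywhere authoritative; the report
computes both the pooled rate and a per-reviewer breakdown. Rater
proficiency ("estimates generally within 15% of weighed values") is
operationalized with a configurable quantile: by default *every* tray must
be within tolerance, the conservative reading; sites that read "generally"
more loosely can lower `pass_quantile`.

## Evaluation statistics

### Bland–Altman agreement

For paired (rater, weighed) meal energies, differences are
`estimate − reference`; the analysis reports the mean difference with a
t-based 95% CI, limits of agreement at mean ± 2·SD (the literal
2-SD convention, not 1.96; the multiplier is a parameter), the count of
observations outside the limits, and the Pearson correlation of differences
against pair means as a check that agreement does not depend on meal size.
Clustering of raters within tray is deliberately ignored here, matching the
method's standard use as a descriptive agreement summary.

### Accuracy calibration

If raters are accurate, `estimate = slope × true + intercept` with slope 1
and intercept 0. The model is a linear mixed model with a random tray
intercept (three raters share each tray, so records cluster within tray),
fitted by REML. Wald t tests with Satterthwaite degrees of freedom test
intercept = 0 and slope = 1; a likelihood-ratio alternative (ML refits) is
available via `test = "lrt"`. A degenerate design with constant true values
leaves the slope unidentifiable and is rejected.

### Inter-rater reliability

The ICC is the between-tray variance over the total variance,
`var_tray / (var_tray + var_residual)`, from a REML mixed model with a
random tray intercept and optional fixed covariates (day, meal). Because
raters enter only through the residual, the same estimator serves the
complete design (every rater rates every tray) and the incomplete clinical
design (each tray rated by a subset of raters). Negative variance
components are truncated at zero. On balanced designs with no covariates
this estimator coincides with the one-way ANOVA method-of-moments
estimator, which the test suite uses as an independent oracle.

The CI method used by the original SAS analyses of this design is
undocumented, so the package's documented choice is a seeded parametric
bootstrap (default 1000 replicates): simulate new responses from the fitted
model, refit, take percentile limits. Exact reproduction of any particular
SAS interval is therefore not claimed.

### Time efficiency

Total calorie-count time is the sum of three task times (pre-meal
verification, post-meal estimation, data entry). The model is

$$\log T \sim \text{method} + \text{day} + \text{session} + \text{meal}
+ (1\,|\,\text{rater})$$

by REML, with no interactions (none were material in this design). On the
log scale the method contrast anti-logs to a ratio of *median* times:
`ratio_pct = 100·exp(β_MCM − β_TM)` is the percent of traditional-method
time the multi-component method needs, and `100 − ratio_pct` the time
saving. The CI anti-logs the Wald interval with Satterthwaite degrees of
freedom. In a fully balanced design the contrast reduces exactly to the
geometric-mean ratio, which the tests exploit. When a degenerate fit (zero
residual variance) breaks the Satterthwaite machinery, the coefficient
table falls back to ordinary-least-squares standard errors with residual
degrees of freedom — the correct limit when the random-effect variance
collapses.

### Method-label resolution

The timing exercise's assignment rules are structural: each session is half
MCM / half TM, and each rater switches method between a day's two sessions.
The bundled 24-row timing table violates these rules as printed (day 1
session 2 has three MCM labels; day 3's two sessions carry identical
labels). `resolve_method_labels()` enumerates, per day, the assignments
consistent with both rules, keeps the minimal-flip candidates, and breaks
ties by minimizing the pooled within-method variance of log total time —
for day 3 this cleanly identifies session 1 as the mislabeled one, since
its label/time pattern is inverted relative to every other session. The
correction is explicit, logged, and opt-in; analyses can be run on printed
or corrected labels. On the corrected table the fitted ratio is 32.7%
(95% CI ≈ 31–34.5%), i.e. a time saving of about 67%, with meal effects
ordered breakfast < lunch < dinner.

## The simulator

The simulator exists so that every statistic above can be exercised, at the
evaluation's own design sizes, without ward data:

* **Trays** — 3–8 items; total tray energy Normal(550, 150²) kcal
  truncated at 150, split across items by normalized Gamma(2) weights;
  serving weights Uniform(60, 350) g. These are field-realistic hospital
  tray magnitudes; no authoritative distribution exists, so they are fixed
  modeling choices, documented here and overridable in `sim_config()`.
* **Consumption** — per item, Beta(1.2, 0.8) scaled to 0–100 with point
  masses 0.05 at 0 and 0.15 at 100 (trays are often untouched or cleaned).
  Leftover weights are derived consistently, so the weighed formula inverts
  the draw exactly.
* **Raters** — `round(clip(true + bias + N(0, σ²), 0, 100))` per item. The
  default σ = 15 percentage points is calibrated so that the SD of the
  rater-minus-weighed *meal energy* difference is ≈ 40 kcal — the agreement
  scale reported for trained raters — and is explicitly a modeling choice,
  not a measured quantity.
* **Designs** — the complete 3 raters × 30 trays (5 days × 3 meals ×
  2 diets) laboratory grid; the incomplete clinical grid (6 raters,
  15 assessments each, every tray rated by exactly 3 raters, built from
  random rater triples and their complements); and the 4 raters × 3 days ×
  2 sessions timing grid with the alternating balanced assignment and
  lognormal task times (traditional-method medians 430/150/860 s, method
  ratio 0.327, meal multipliers 0.85/1/1.15).

One master seed spawns a named substream per stage and unit, so identical
configurations reproduce identical data sets regardless of caller RNG
state, and adding a stage never perturbs earlier draws.

What passing simulation-based tests shows — and what it does not: the
generator draws independent Gaussian item errors and lognormal task times;
real raters drift, err asymmetrically near empty and full plates (the
clipping reproduces part of this), and face foods of genuinely different
difficulty (stews, condiments). Recovery of generating parameters under the
simulator therefore validates the *estimators*, not the field accuracy of
any particular ward's raters.

## Numerical and design choices

* REML everywhere variance components are estimated; ML only inside
  likelihood-ratio tests. Negative components truncate at 0.
* Satterthwaite degrees of freedom for fixed-effect tests and CIs, with the
  OLS fallback described above for zero-variance corners.
* Limits of agreement use ±2·SD by default (`loa_multiplier` to change).
* Percentages are integers; fractional entry is an error, never rounded.
* Status lifecycle of a form moves only forward
  (generated → verified → recorded → finalized); partial percentage entry
  is allowed to support shift handoffs.
* Menu cycles are keyed by integer cycle day, not calendar date; mapping
  dates to cycle days is site configuration, since cycle length varies by
  site.
* Problem sizes used in the test suite match the evaluation designs
  (n = 90 assessments, 30 trays, 24 timing records); replicate counts
  (200 agreement replicates, 500 reliability replicates, 100–150 coverage
  replicates) were chosen to keep Monte-Carlo error comfortably inside the
  asserted bands.

## Known limitations

* The ICC bootstrap CI is percentile-based and can be short in very small
  designs; profile or chi-square-based intervals are not implemented.
* The accuracy and ICC models assume homoscedastic Gaussian errors on the
  kcal scale; heavy-tailed rater error would call for robust variants.
* The label resolver assumes exactly two sessions per day and an even
  number of raters — the structure of the timing design it serves.
* Micronutrient columns are carried through the accounting engine
  unvalidated beyond non-negativity; accuracy claims attach to energy only,
  which is the only output the evaluation design measured.
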