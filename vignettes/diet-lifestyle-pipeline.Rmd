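---
title: "Methods: index scoring, outcome derivation and the association pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: index scoring, outcome derivation and the association pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietlife)
```

This vignette is the package's own account of its methods: the scoring
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where the underlying
instruments or common practice leave room.

## The three indices

**Mediterranean diet score (MDS).** Nine components, each 0/1, scored
against *cohort-internal medians*: this makes the score a relative ranking
within the analytic sample, not an absolute adherence measure. The at-median
boundary counts as adherent (`value >= median` scores 1 for beneficial
components), the convention of the original sum-score formulation; dairy and
combined red + processed meat score 1 strictly *below* the median; ethanol
scores 1 in the moderate window `[5, 25)` g/d, so both abstainers and
heavier drinkers score 0. Because medians are cohort-internal, the score is
invariant to any cohort-wide shift of a single component (tested), and it
must be computed on the final diet-only analytic sample, after exclusions.
A zero-SFA denominator with positive MUFA is treated as an infinite ratio
(adherent whenever the cohort median is finite) and reported via a message;
0/0 is treated as 0.

**Modified WCRF/AICR score.** Six of the nine cancer-prevention
recommendations are scored (body weight, physical activity, energy-dense
food and sugary drinks, plant foods, red and processed meat, alcohol), each
1 / 0.5 / 0; the salt, supplement and breastfeeding recommendations are not
implemented because the data the package targets do not collect them, so
totals span 0–6 rather than 0–7. Cut-points live in a serializable
configuration (`default_cutpoints()`), with defaults following the
standardized scoring conventions: full BMI compliance at 18.5–24.9 kg/m²
with 25–29.9 partial; activity ≥ 150 moderate-equivalent min/wk full,
75–149 partial; plant foods full at ≥ 400 g/d fruit + vegetables +
legumes *and* ≥ 30 g/d fiber; red meat < 500 g/wk with processed meat
< 21 g/wk full and < 100 g/wk partial; alcohol full compliance at complete
abstention with partial up to one standard drink (10 g ethanol, the
Australian standard, since the package targets Australian-instrument data).
Legumes count inside the fruit-and-vegetable category for this index.

**Extended Healthy Lifestyle Index (EHLI).** The five classic
healthy-lifestyle components (smoking never/former/current → 1/0.5/0,
alcohol, activity, BMI, fruit and vegetables) plus four dietary extensions
(weight-gain-promoting drinks, red + processed meat, unprocessed
grains/legumes, dairy), each 1 / 0.5 / 0, total 0–9. Legumes count inside
the grain category here, not in fruit-and-vegetables. Because BMI,
activity, alcohol, meat and sugary drinks appear in both WCRF/AICR and
EHLI, the two totals are positively rank-correlated by construction; the
test suite asserts this on generated cohorts.

Records missing a lifestyle ingredient (BMI, activity, smoking) are flagged
`*_unscoreable` with a missing total rather than dropped: sample definition
belongs to the exclusion cascade, not the scorers.

**Tertiles.** Index totals are cut at their empirical 1/3 and 2/3 type-7
quantiles, with tertile 3 denoting good adherence. Values tied with a
boundary quantile all go to the *lower* tertile (`1 + (x > q1) + (x > q2)`),
a deterministic and easily auditable rule for the heavily tied discrete
totals these indices produce. Note the consequence: with boundary ties the
top group can only be as large as or smaller than n/3, so reported
good-adherence proportions above one third must come from tie conventions
that push boundary ties upward (as some statistical systems do); the
package renders whatever tertile vector it is given and keeps the rule
explicit rather than hidden.

## Outcome derivations

HOMA-IR is glucose (mmol/L) × insulin / 22.5, with missing inputs
propagating and non-positive inputs an error naming the record. BMI and
waist-to-hip ratio come from nurse-measured anthropometry.

FACIT: 43 items in 0–4 across five domains (7/7/6/7/16), reverse-scored
items mapped 4 − x. A subscale is prorated — sum of answered ×
items/answered — when *more than* 50 % of its items are answered, else
missing; the overall score (0–172) is the sum of subscales when more than
80 % of all 43 items are answered. Prorated scores are kept at full
precision: rounding before regression would discard information for no
benefit. The reverse-scored item set is instrument-version-dependent and
therefore supplied as a scoring key (`default_facit_key()`); the package
validates the key's completeness (7/7/6/7/16, no duplicates) rather than
hard-coding item lists. The default key is a synthetic convention matched
to the package's own generator, and real-data users must supply their
instrument's key.

HADS: two 7-item subscales in 0–3, the same proration thresholds reused
verbatim (one rule, two instruments), severity bands normal 0–7, mild
8–10, moderate 11–14, severe 15–21. Prorated fractional totals fall in the
band they do not exceed (< 8 normal, < 11 mild, < 15 moderate), which
partitions the whole interval with no gaps.

## Exclusion cascade

Order is fixed: implausible energy → missing demographics → missing
physical activity; each excluded record carries exactly the first failing
reason. Two energy-bound modes exist: `fixed` (2568–17 031 kJ/d, the
operative numbers; at the thermochemical 4.184 kJ/kcal these are ≈ 614 and
≈ 4070 kcal/d) and `data_driven` (`exp(mean(log E) ± 3 sd(log E))`).
`fixed` is the default because it makes results exactly reproducible
across samples; the data-driven rule is computed over all questionnaire
completers, since nothing in the rule's definition says otherwise.
"Missing demographics" is operationalized as missingness in any covariate
of the MDS model's adjustment set (age, education, marital status,
smoking, comorbidities) and is configurable, because the field list is a
modeling decision, not a property of the data. Records missing only
physical activity stay in the diet-only sample and leave the
diet + lifestyle sample, giving the two analytic sample sizes.

## Association models

Exposures are z-standardized with the sample-SD (n − 1) convention —
chosen over the population-SD convention because every downstream fit uses
n − 1 residual degrees of freedom; the tests pin the convention down
(`{2,4,6} → {−1,0,1}`). Standardization happens inside each model's
complete-case sample, so "per SD" always refers to the sample actually
modeled. Models are ordinary least squares with per-index covariate sets:
MDS adjusts for age, total energy (kcal/d), education, marital status,
smoking, comorbidities, physical activity and BMI; WCRF/AICR drops BMI and
activity; EHLI additionally drops smoking — a covariate that is part of
the exposure score would be adjusted away. For the same reason BMI as an
*outcome* is structurally skipped for WCRF/AICR and EHLI, so the default
grid fits 49 of its 51 cells. The Bonferroni family nevertheless stays at
the full 51 (3 indices × 17 outcomes): correcting at the enumerated family
size is the conservative choice and the family size is an explicit
parameter (`grid_config(family = )`).

The four glycemic outcomes (HbA1c, fasting insulin, fasting glucose,
HOMA-IR) are modeled as natural logs, with estimate and CI exponentiated:
their residuals are right-skewed on the raw scale, and the exponentiated
coefficient reads as a multiplicative change per SD. Non-positive values
under a log model raise an error rather than triggering a hidden offset.
Categorical covariates use indicator coding with fixed reference levels
(education "high school or less", marital status "partner", smoking
"never", comorbidities "0"). Complete-case analysis per model, no
imputation: per-row n is reported and varies across outcomes.

Descriptive tertile comparisons use chi-square for categorical variables
and ANOVA or Kruskal–Wallis for continuous ones. The normality gate is
configuration rather than a per-dataset hypothesis test: by default the
four log-modeled glycemic outcomes go to Kruskal–Wallis and everything
else to ANOVA, while the Shapiro–Wilk p-value of the ANOVA residuals is
computed and reported alongside so the gate can be audited.

## Index agreement

Spearman ρ uses average ranks for ties with the t-approximation p-value
(exact at |ρ| = 1); the tests verify equality with `cor.test`. Weighted
kappa uses linear (Cicchetti–Allison) disagreement weights by default —
the default of the statistical system most epidemiology groups report
using — with quadratic weights by flag; the p-value tests κ = 0 with the
Fleiss–Cohen–Everitt large-sample null variance. Both statistics are
implemented in-package (no installed dependency provides weighted kappa)
and are verified against an independently computed 3 × 3 oracle, a
permutation null, and chance-level behaviour at n = 10 000.

## The synthetic cohort generator

The generator emulates the *marginal* baseline structure of a severely
obese endometrial-cancer trial population: BMI ~ N(47.5, 9.3²) truncated
at 30 kg/m² (the eligibility floor), about 66 % aged ≥ 50, 78 %
physically inactive (zero-inflated activity minutes), lognormal intakes
and glycemic markers matched to printed medians/IQRs (e.g. glucose median
5.9 mmol/L, insulin median 19 on its as-recorded scale — the generator
reproduces that numeric scale without asserting unit correctness), and
total energy lognormal with meanlog 8.797 and sdlog 0.315, whose ±3 SD
log-range reproduces the 2568–17 031 kJ/d plausibility window.
Dependence is induced by a Gaussian copula with exchangeable blocks:
ρ = 0.2 across intake variables (a modest positive correlation typical of
food-frequency data), ρ = 0.5 within anthropometry and ρ = 0.4 within the
glycemic panel — published baseline tables report no joint structure, so
these are deliberate, documented conventions, not estimates.
Questionnaire items come from per-domain latent severities passed through
proportional-odds thresholds, with the threshold offset solved numerically
so domain means hit their configured targets; this makes planted domain
means controllable while keeping item-level responses integer and ordinal.

What the generator does *not* emulate: the real joint distribution of
intakes with outcomes (beyond the copula blocks), item-level response
styles, informative missingness (missingness is MCAR at configured rates),
or any true exposure–outcome structure — effects exist only where
`plant_effect()` writes them. Passing tests therefore demonstrate that the
*pipeline machinery* is correct (scoring arithmetic, exclusion logic,
estimator calibration, coverage), not that any scientific association
holds in real data.

`plant_effect()` overwrites one outcome as
`intercept + β·z(exposure) + covariates + N(0, noise_sd)` on the modeling
scale (log scale for glycemic outcomes), which makes it the generative
twin of the fitted models: with `noise_sd = 0` refitting recovers β to
numerical precision, and with noise the estimator is unbiased with 95 %
CI coverage — both verified by simulation in the test suite.

## Problem sizes and numerical tolerances

The test suite uses cohorts of 150–1500 records, 500-replicate simulations
for bias and CI coverage, 1000 replicates for the type-I-error rate, and
10 000 fuzz cases for score-range properties — sizes chosen so Monte-Carlo
standard errors are small enough for 3-SE acceptance bands while the whole
suite runs in well under a minute per file. Exact arithmetic claims
(noiseless recovery, closed-form slopes, oracle kappas) are tested at
1e-8–1e-12; statistical claims at 3 Monte-Carlo SEs. Known limitations:
cut-point defaults are field conventions, not the (unpublished) tables a
specific study may have used, so absolute WCRF/EHLI adherence proportions
will shift with the configuration; the MDS is sample-relative by design;
and the generator's copula blocks are conventions that should be replaced
by estimated structure when real data are available.
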