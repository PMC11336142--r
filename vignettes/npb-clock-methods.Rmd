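---
title: "Methods: building and validating a non-invasive physiology-and-behavior age clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a non-invasive physiology-and-behavior age clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long-term field studies of wild animals accumulate annual records of
behavior, reproduction, social status and fecal physiology for known
individuals across their whole adult lives. None of these measurements
requires capturing or sampling tissue, which makes them attractive raw
material for a *biological age clock*: a supervised model that predicts an
individual's chronological age from its trait profile, so that the residual
— how much older or younger an individual *looks* than it is — can be read
as a marker of biological aging. `npbclock` implements such a clock for
long-format individual-year panels, together with the downstream
epidemiology: does looking old-for-age predict death, and is it shaped by
early-life adversity?

## The pipeline, stage by stage

### Trait screening

Each trait is screened for linear and quadratic age associations with a
two-stage procedure. First, a base covariate model is selected by
exhaustive AIC search over all subsets of the trait's candidate covariates
(at most 10, so at most 1024 fits), with the tie-break that any model
within 2 AIC units of the minimum loses to the model with fewer estimated
parameters. Second, centered age and centered-age-squared are added to the
selected model, and the trait is retained for the clock when either term is
significant at alpha = 0.05 per term (an OR combination across the two
terms; the per-term reading is deliberate and is what the calibration tests
check).

Model families follow the trait kind: Gaussian linear mixed models with an
individual random intercept for continuous traits, binomial GLMMs for
binary traits, and a plain multinomial (softmax) regression for three-level
categorical traits. Two deliberate simplifications relative to common field
practice: the random-effect structure is held fixed during the AIC search
(comparing AIC across random-effect structures requires ML/REML care that
is easy to get wrong), and the multinomial family carries no random effect
and uses likelihood-ratio rather than Wald tests — its fitter is a small
BFGS maximizer built into the package because no multinomial GLM package is
assumed. Age is centered at the panel mean before squaring to reduce
collinearity; screening coefficients are therefore reported on the
centered-age scale.

### Inclusion filters and two-phase imputation

Individual-years observed fewer than 60 days, and individual-years missing
at least 65% of the clock traits (32 of 49 at the default scale), are
dropped before imputation. Both thresholds are inclusive on the drop side
(exactly 59 days drops; exactly 32 missing drops).

Missing cells are then completed in two phases. Phase 1 fills a missing
trait-year from the same individual's immediately adjacent years: the mean
of the two neighbors for continuous traits when both are observed, a
seeded random choice between them for non-continuous traits, and a simple
carry when only one neighbor is observed. Only *originally observed*
values may serve as neighbors — fills never propagate, which prevents long
constant runs when several consecutive years are missing.

Phase 2 is chained predictive mean matching (PMM). Records are first
assigned to five test folds so that each individual's years are spread as
evenly as possible across folds (round-robin over a seeded random fold
order), and imputation is run on each training partition and each test
partition *separately* — no information crosses the split, which is the
property that makes downstream generalization estimates honest, and which
the leakage tests verify literally (perturbing a training cell cannot
change any test-partition value). Within a partition, each incomplete
column is regressed linearly on all other columns (categorical predictors
one-hot encoded), and each missing cell draws a donor among the `k = 5`
observed rows with the closest predictions, with probability proportional
to `1/(rank + 1)`. Imputed values are therefore always observed values of
their column. Age is never in the predictor matrix. Five imputations per
split give 25 train/test set pairs. The reference implementation in the
field uses spline-based flexible transforms inside its PMM; this package
uses linear predictors, a documented divergence — the scientific content
(donor mechanism, split isolation) is preserved.

### The random-forest clock

The clock is a regression random forest (2000 trees in production; the
acceptance tests use 500, which the build contract itself prescribes for
CI) mapping the centered and standardized clock traits to known age.
Because no random-forest package could be assumed in the target
environment, the forest is implemented in C++ inside the package:
bootstrap resampling, exhaustive variance-reduction splits over `mtry`
randomly drawn features per node, node size 5, out-of-bag prediction
accumulation, and a deterministic RNG per seed. `mtry` is tuned once on
the split-0 training sets by maximizing out-of-bag R² over a small grid
and reused across splits (tuning per split is available via
`tune_per_split`-style configuration of the grid but is not the default).

Each record is predicted by the five models of the one split where it is a
test record, and the five per-imputation predictions are averaged.
Reported metrics: R² as the *squared Pearson correlation* between
predicted and known age (the alternative `1 - SSE/SST` differs under
miscalibration; the choice is recorded in the metrics output), median
absolute error in years, and the OLS slope of predicted on known age —
below 1 whenever predictions are compressed toward the mean, which is the
expected behavior for noisy traits.

*Delta age* is predicted minus known age. *Relative age* is the residual
of a pooled OLS regression of predicted on known age; it sums to zero and
is uncorrelated with known age by construction, and the two quantities are
related by the affine identity
`relative = delta - (intercept + (slope - 1) * known)`. Repeatability of
relative age is the intraclass correlation from a random-intercept model
grouped by individual, clamped to [0, 1]; on balanced fixtures it
reproduces the one-way ANOVA ICC closed form, which the tests use as an
independent oracle. A restricted clock variant drops the traits flagged
`mortality_linked` in the registry and refits everything downstream.

### Survival and adversity models

Mortality models are Cox proportional-hazards fits on counting-process
records, Efron tie handling, delayed entry at the first observed adult
year. The lifetime model uses one interval per individual with her
lifetime mean relative age; the annual (time-varying) model uses one
interval per predicted year with that year's relative age and
cluster-robust (grouped sandwich) standard errors by individual. A death
whose final year failed the 60-day filter contributes no event — exactly
the bookkeeping the filters imply. The fits are backed by
`survival::coxph` behind the package's interface; an independent
hand-written Efron partial-likelihood maximizer lives in the test suite so
the two routes are always compared on fixtures.

Early-life adversity is scored from six sources — maternal death,
close-in-age sibling, drought, maternal social connectedness, maternal
rank, group size — with the three continuous sources binarized at the most
adverse population quartile (thresholds inclusive on the adverse side:
connectedness and rank at or below the 25th percentile, group size at or
above the 75th). The cumulative index (0-6) enters a linear mixed model of
annual delta age with individual random intercepts, always controlling for
chronological age plus current rank, group size, and rainfall anomaly; a
multivariable mode uses the six sources unbinned instead. If the random
effect is unestimable the model falls back to OLS with by-individual
sandwich SEs and says so. Finally, a joint Cox fit of relative age and the
cumulative index reports an attenuation diagnostic (ratio of the
relative-age log-hazard with vs without adversity), the quantity of
interest when adversity confounds the clock-mortality association.

## The synthetic cohort: what it emulates and what it does not

Field data of this kind cannot be redistributed, so the package carries a
generative stand-in with known ground truth. Its defaults state the world
of a long-running baboon field study: 319 adult females entering at age 4,
administrative censoring at 27, 49 traits (38 continuous, 7 binary, 4
three-level), 26% missing cells, baseline annual mortality hazard 0.093.

Continuous traits follow
`b0_i + beta1 * (a + lambda * f_i) + beta2 * (a + lambda * f_i)^2 + eps`,
with per-trait coefficients realizing six age-shape classes (convex,
linear decreasing, linear increasing, plateauing, ascending, concave) via
sign patterns and vertex placement inside the observed age range; binary
and categorical traits use the analogous linear predictor through logistic
and ordinal-logistic links. The latent frailty `f_i` (SD 1 year by
default) enters traits as an *age offset* — an individual with `f_i = 1`
looks one year older than she is — which is precisely what makes
"predicted minus known age" an estimator of frailty, and it multiplies the
mortality hazard through `exp(0.3 * f_i)`. Early-life adversity adds 0.15
years of frailty per experienced source, so adversity, old-for-age
predictions and death are coupled the way the scientific hypothesis
requires. Adversity records exist for 80% of individuals, mirroring
incomplete early-life data in real cohorts.

Two generator constants were chosen once, where the stated world was
silent, and are not revisited: independent exponential dropout at 0.05/yr
(administrative censoring alone would kill ~88% of the cohort in
observation; with dropout the simulated cohort dies ~60% of the time and
averages ~6.9 adult years per female, the closest realistic match to the
reference cohort's 51% deaths and 7.5 years), and trait noise of 0.3 SD
individual intercepts plus 0.5 SD residual, which puts single-trait age
signal in the weak-but-present regime the screening power analysis
assumes.

What the generator does *not* emulate: social-network structure, temporal
autocorrelation of environments, trait-trait correlations beyond the
shared age/frailty signal, and the blocky stream-wise missingness of real
field data. The last point matters for one published bookkeeping detail:
with independent (MCAR) missingness, most missing cells have an observed
adjacent-year neighbor, so phase-1 filling covers a much larger share of
the missing mass than in the real data (where whole data streams are
absent for year ranges and the phase-1/phase-2 split was roughly 10%/16%).
A green imputation test therefore establishes rule-level correctness and
split isolation, not the field distribution of fill sources.

## Numerical choices and degenerate inputs

* Standardization uses the sample SD (n − 1). The leakage-safe default
  computes statistics on each training partition and applies them to its
  test partition; `standardize_scope = "global"` reproduces pooled
  standardization.
* Zero-variance traits standardize to centered-only (scale 1) with a flag;
  constant traits are screened as unfit rather than erroring the whole
  screen; constant covariates make Cox fits fail fast as non-identifiable.
* PMM donor ties in predicted value break by row order, then the seeded
  draw; `k` larger than the observed pool shrinks to the pool.
* All stage seeds derive from one master seed via a labeled sub-stream
  hash (`derive_seed`), so any stage can be reproduced in isolation and
  nothing shares a stream by accident.
* Quartile thresholds for adversity scoring are inclusive on the adverse
  side, making scoring deterministic under ties.

## What a green acceptance run establishes

The acceptance tests are property-based: exact rule fixtures; equivalence
of PMM, Cox and repeatability against brute-force oracles; screening
type-I error within [0.03, 0.07] and power above 0.9 at 0.1 SD/yr
(n ≈ 2400); clock recovery at the default scale (R² ≥ 0.4, compression
slope < 1, frailty correlation ≥ 0.3 at 500 trees); survival recovery over
50 scaled-down replicates (HR > 1 in ≥ 80% under a real frailty-mortality
link; ≤ 7/50 rejections under the null, the 99.5th percentile of
Binomial(50, 0.05) fixed before running); adversity-effect coverage in
≥ 90% of 200 LMM replicates and attenuation under full confounding; and
literal leakage isolation plus restricted-clock agreement (r > 0.8). The
adversity-recovery replicates use an idealized clock (delta age = frailty
plus noise) because 200 full forest pipelines would exceed any reasonable
test budget ~100-fold; the estimator under test is exercised identically,
and the full simulate-to-LMM path runs once at default scale. None of
these numbers certify performance on real field data — they certify that
the machinery recovers known truth in the stated world.

## Known limitations

* The PMM engine uses linear predictors, not the spline-based transforms
  of the field-standard imputation package.
* The multinomial screen has no individual random effect; repeated
  three-level measurements are treated as independent in that family only.
* No elastic-net or Gaussian-process clock variants, no competing-risks or
  frailty-term Cox models, and no plotting beyond what the artifact files
  allow downstream.
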