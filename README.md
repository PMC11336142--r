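# npbclock

Biological-age clocks from non-invasive physiology and behavior, for
longitudinal studies of wild animals.

Long-term field studies follow known individuals for decades, recording
annual panels of behavioral and physiological traits — activity budgets,
social integration, dominance rank, reproductive performance, fecal
hormone and parasite measures — without ever capturing an animal.
`npbclock` turns such a panel into an age-predicting clock and runs the
downstream epidemiology. It is aimed at biologists and biostatisticians
working with individual-year trait panels who want to measure
heterogeneity in biological aging and test its causes and consequences.

## The model

Given standardized traits $x_{it}$ for individual $i$ in her year of life
at age $a_{it}$, a random-forest regression $\hat a_{it} = f(x_{it})$ is
trained to predict chronological age. Two derived quantities carry the
biology:

* **delta age** $\Delta_{it} = \hat a_{it} - a_{it}$, and
* **relative age** $r_{it} = \hat a_{it} - (\beta_0 + \beta_1 a_{it})$,
  the residual from the pooled regression of predicted on known age —
  positive values mark individuals who look old for their age after
  removing the clock's calibration (compression) line.

Relative age then enters Cox proportional-hazards models of adult
mortality — a lifetime model (one record per individual, covariate = mean
relative age) and a time-varying counting-process model (one record per
year, cluster-robust SEs) — and delta age enters linear mixed models
testing whether a cumulative early-life adversity index (0–6 adverse
conditions, continuous sources binarized at the most-adverse population
quartile) predicts looking old-for-age.

The full pipeline: inclusion filters (≥ 60 observation days, < 65% of
traits missing) → mixed-model age screening with exhaustive-AIC covariate
selection → adjacent-year filling → five leakage-safe train/test splits →
chained predictive-mean-matching imputation run separately per partition
(5 imputations × 5 splits = 25 completed set pairs) → forest training with
out-of-bag `mtry` tuning → prediction averaging → survival and adversity
models. A synthetic-cohort generator with known latent frailty provides
ground truth for every stage; see the methods vignette
(`vignettes/npb-clock-methods.Rmd`) for the generative model and all
numerical conventions.

## Worked example

```r
library(npbclock)

cfg <- pipeline_config(
  sim = sim_config(n_individuals = 150L, n_continuous = 16L, n_binary = 3L,
                   n_categorical3 = 1L),
  seed = 7, m = 2L, ntree = 200L, tune_ntree = 60L, run_screen = FALSE,
  restricted = FALSE)
res <- run_pipeline(cfg)
```

which prints (exact output of this configuration):

```
clock R^2 = 0.95, median error = 0.70 years, slope = 0.92
repeatability of relative age = 0.45
<cox_result> 83 events, model SEs
             covariate coefficient hazard_ratio   se ci_low ci_high p_value
 lifetime_relative_age       0.326         1.39 0.14   1.05    1.82  0.0194
cumulative adversity effect on delta age: 0.146 yr/source (p = 0.040)
```

Reading the numbers: the clock explains 95% of age variance in this
(deliberately clean) synthetic cohort with a median error of 0.70 years;
the slope of 0.92 < 1 shows the usual prediction compression. Individuals
whose lifetime mean relative age is one year older face a 1.39-fold higher
mortality hazard — the generator couples latent frailty to both traits and
death, and the clock recovers that link. Each source of early-life
adversity adds 0.146 years to delta age, against a generating value of
0.15 years per source. On real field data the clock's R² is far lower
(traits carry much less collective age signal than this synthetic world);
the pipeline mechanics are identical.

The command-line interface wraps the same functions:

```sh
Rscript inst/cli/npbclock.R simulate --config cfg.yaml --seed 3 --out out/
Rscript inst/cli/npbclock.R run      --config cfg.yaml --seed 3 --out out/
```

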