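# musclebone

Muscle and bone are mechanically and biochemically coupled: muscle loading
drives bone remodelling, and bone-derived factors may feed back on muscle.
Whether these effects persist over years, and in which direction they run,
is a longitudinal question that simple regressions answer badly — they
confuse within-visit associations, carry-over of each tissue's own past,
and genuine lagged cross-effects. `musclebone` is an R package for
epidemiologists and musculoskeletal researchers analysing three-wave DXA
body-composition cohorts (lean mass and areal BMD of the arms and legs,
measured at roughly 0, 48 and 120 months) who want those components
separated explicitly.

## What it implements

At its core is a three-wave **cross-lagged panel model** over the observed
measures of one region, with muscle $M_t$ and bone $B_t$ at visits
$t \in \{V0, V3, V5\}$:

$$
B_t = \beta_t M_t + \gamma_{MB} M_{t-1} + \rho_B B_{t-1}
      + \mathbf{c}_B^\top \mathbf{x} + \varepsilon_{B,t},
\qquad
M_t = \rho_M M_{t-1} + \gamma_{BM} B_{t-1}
      + \mathbf{c}_M^\top \mathbf{x} + \varepsilon_{M,t},
$$

with the autoregressive coefficients $\rho_M, \rho_B$ constrained equal
across the two lag periods and baseline covariates $\mathbf{x}$ predicting
every endogenous variable. The model is fitted by normal-theory maximum
likelihood on the sample covariance matrix via the RAM representation
$\Sigma(\theta) = (I-A)^{-1} S (I-A)^{-\top}$, with analytic gradients, a
quasi-Newton fallback on non-convergence, and delta-method standardized
coefficients. Around the engine:

- **Fit assessment**: $\chi^2$, SRMR, RMSEA with noncentral 90% interval,
  Bentler–Bonett NFI, and the two-of-four adequacy rule.
- **Mediation**: decomposition of lagged effects into direct and indirect
  components over all parallel mediation routes, with delta-method SEs,
  percent-of-total and indirect/direct ratio reporting (including the
  `Div by 0` flagging convention).
- **Descriptives**: per-visit summaries with random-intercept
  repeated-measures contrasts, per-participant percent change,
  annualization, and LMS reference z-scores.
- **Sensitivity**: general linear models of baseline predictors on
  subsequent change, constraint-validity correlations, and a demonstration
  of the spurious association induced by timing the predictor at the start
  of a change window.
- **Synthetic cohorts**: a generator whose generative process *is* the
  canonical model, calibrated to realistic cohort moments, so every stage
  is testable end to end.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted models, and `autoplot()` methods for the main
result types.

## Worked example

```r
library(musclebone)

cfg    <- synth_config(n_participants = 1286, seed = 7)
cohort <- simulate_cohort(cfg)          # wide three-visit table
ds     <- build_analysis_dataset(cohort) # side selection, indices, filters
attr(ds, "counts")
#>                    read excluded_glucocorticoid     excluded_incomplete
#>                    1286                       0                      48
#>                retained
#>                    1238
```

Visit-level change in leg lean mass, with the repeated-measures contrasts:

```r
visit_summary(ds, "leg_LM")
#> <visit_summary> leg_LM
#>   visit  mean    sd     n
#> 1 V0    10.5   1.54  1238
#> 2 V3    10.4   1.57  1238
#> 3 V5     9.71  1.55  1238
#>   contrast estimate     se  p.value
#> 1 V3 - V0    -0.141 0.0170 1.44e-16
#> 2 V5 - V0    -0.789 0.0170 0

pc <- percent_change(ds, "leg_LM")      # mean of per-participant ratios
pc$mean_pct_change                       #> -7.45
annualize(pc$mean_pct_change, 120)       #> -0.745  (% per year)
lms_zscore(mean(ds$V0_leg_LMI), lms_reference(0.118, 3.457, 0.147))
#> -0.06   (cohort baseline sits at the reference median)
```

Fit the cross-lagged model and inspect the structural paths:

```r
spec <- build_clpm_spec("leg_LM", "leg_BMD",
                        covariates = c("age", "height", "weight",
                                       "grip", "smoking", "diabetes"))
fit <- fit_clpm(spec, ds)
td  <- tidy(fit)
td[!grepl("^b_", td$label), ]            # structural edges only
#>     predictor    outcome estimate std_estimate  std_se    std_p
#> 1   V0_leg_LM V0_leg_BMD  0.03354      0.35460 0.02489 4.76e-46
#> 4   V0_leg_LM V3_leg_BMD  0.01195      0.12665 0.02317 4.59e-08
#> 8   V0_leg_LM  V3_leg_LM  0.93594      0.92265 0.00586 0.00e+00
#> ...

fit_indices(fit)
#> <fit_index_set> chi2 = 5.937 (df = 6, p = 0.4303), SRMR = 0.0030,
#>   RMSEA = 0.0000 [0.0000, 0.0367], BB-NFI = 0.9995 -> adequate (4/4 criteria)
```

The contemporaneous standardized effect (0.35) dwarfs the one-lag
cross-effect (0.13), and the decomposition shows most of the lagged total
travels through mediating routes rather than the direct edge:

```r
decompose(fit, "V0_leg_LM", "V3_leg_BMD")
#>   direct indirect total pct_direct pct_indirect ratio
#> 1  0.127    0.216 0.343       36.9         63.1  1.71
```

The whole analysis — descriptives, nine region/metric model variants, fit
table, decomposition and sensitivity models — runs from one configuration:

```r
run_pipeline(list(synthetic = list(n_participants = 1286, seed = 7)),
             out_dir = "results/run1")
```

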