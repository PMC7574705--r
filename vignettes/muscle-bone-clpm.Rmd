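---
title: "Cross-lagged panel models of muscle-bone relationships: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel models of muscle-bone relationships: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(musclebone)
```

`musclebone` implements a longitudinal path analysis of the reciprocal
relationship between skeletal muscle (DXA lean mass, kg) and bone (DXA areal
BMD, g/cm^2) measured at three study visits, together with the descriptive,
mediation and sensitivity analyses that surround it, and a calibrated
synthetic-cohort generator so that every stage is testable without access to
cohort data. This vignette is the package's account of the statistical
machinery: the model and its assumptions, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data can and cannot
tell you about behaviour on real cohorts.

## The cross-lagged panel model

For one limb region, let $M_t$ and $B_t$ be the muscle and bone measures at
visits $t \in \{V0, V3, V5\}$ (approximately 0, 48 and 120 months). The
canonical model, built by `build_clpm_spec()`, is an observed-variable path
model:

* **Contemporaneous paths** $M_t \to B_t$ at each visit (three free
  coefficients $\beta_{t}$, in g/cm^2 per kg). Within a visit the direction
  muscle-to-bone is a modelling convention: simultaneous associations cannot
  be oriented from covariance data alone.
* **Cross-lagged paths** $M_t \to B_{t+1}$ ($\gamma_{MB}$) and
  $B_t \to M_{t+1}$ ($\gamma_{BM}$), one per lag period, four free
  coefficients in total.
* **Autoregressive paths** $M_t \to M_{t+1}$ and $B_t \to B_{t+1}$, each
  pair sharing a single label (the equality constraint across the two lags
  that buys two degrees of freedom and stabilizes estimation).
* **Disturbance variances**, one per endogenous variable.
* **Covariates** (age, height, weight, ancestry, arthritis, prior fracture,
  alcohol, smoking, diabetes, walking, grip strength, hospitalization) enter
  as a freely inter-covarying exogenous block with a directed path from
  every covariate to all six endogenous variables.

The model is held in reticular-action form: a directed-coefficient matrix
$A$ and a symmetric matrix $S$ of variances/covariances imply
$\Sigma(\theta) = (I-A)^{-1} S (I-A)^{-\top}$ (`implied_covariance()`).
Because the directed graph is acyclic, $I-A$ is always invertible, and
$\Sigma$ is positive definite whenever $S$ is.

Only the covariance structure is modelled; means are saturated and never
enter the fit. Estimation is normal-theory maximum likelihood on the sample
covariance matrix $S_N$ (`ml_discrepancy()`):

$$F(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}(S_N \Sigma(\theta)^{-1})
  - \log|S_N| - p .$$

The exogenous block's variances and covariances are profiled at their
sample values, which is their exact ML solution in a model where every
covariate predicts every endogenous variable; they still count as free
parameters in the degrees-of-freedom ledger, so the accounting matches the
conventional $df = p(p+1)/2 - q$.

### Degrees of freedom

The endogenous block alone has 21 distinct moments and 15 free parameters,
hence $df = 6$; adding covariates changes both counts equally. Published
three-wave analyses of this design report $df = 5$; the extra parameter
there is not documented. `build_clpm_spec(..., free_v3_disturbance_cov =
TRUE)` frees the disturbance covariance between the two mid-study variables
and reproduces $df = 5$ for users who want that accounting; the engine
always reports its computed df and never adjusts it silently.

### Optimization

The free parameters mix very different units (kg, g/cm^2, covariate units
and their squares), so the search runs in a unit-scaled space: each directed
coefficient is scaled by $SD(\text{target})/SD(\text{source})$ and each
variance by the variable's sample variance, taken from $S_N$. The objective
has an analytic gradient (standard RAM algebra:
$\partial F/\partial A = 2 B^\top W \Sigma$, $\partial F/\partial S =
B^\top W B$ with $B = (I-A)^{-1}$ and
$W = \Sigma^{-1} - \Sigma^{-1} S_N \Sigma^{-1}$). Starting values are
identity-scaled: autoregressive labels 0.8, all other structural
coefficients 0, variances at their sample values. The primary optimizer is
`nlminb` with positivity bounds on variances; on non-convergence a BFGS
restart with an enlarged evaluation budget runs and is recorded in the
convergence log (`fallback_used`). If a free disturbance covariance drives
$S$ non-positive-definite during the search the objective returns a large
penalty; with the default spec this cannot happen. A failure after the
fallback is an explicit error, never a silent result.

Standard errors are the inverse observed information at the optimum scaled
by $2/(N-1)$ (Wishart convention; $2/N$ when `chi2_multiplier = "N"`), with
normal-reference p-values. Standardized coefficients multiply each estimate
by the ratio of model-implied SDs, with delta-method SEs computed from a
numerical Jacobian of the standardization map — implied, not marginal, SDs,
which is why published standardized/unstandardized pairs computed from
marginal table SDs agree only to about two decimals.

## Fit assessment

`fit_indices()` computes $\chi^2 = (N-1)\,F_{\min}$ with its central
chi-square p-value, SRMR (root mean square of correlation-scale residuals
over the $p(p+1)/2$ unique elements), RMSEA
$\sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$ with a 90% interval obtained by
inverting the noncentral chi-square distribution in the noncentrality
parameter (bisection to $10^{-8}$), and the Bentler-Bonett normed fit index
against an independence model (all covariances zero, variances free,
including the covariate block) fitted by the same engine. The adequacy rule
is two-of-four: nonsignificant $\chi^2$, RMSEA upper bound < 0.08,
SRMR < 0.05, NFI > 0.95. The 90% level for the RMSEA interval is the
conventional choice; it is a parameter of `fit_indices()`.

## Mediation decomposition

A lagged muscle-to-bone effect can travel along the direct cross-lag edge or
through mediating routes (through the lagged muscle measure, through the
contemporaneous bone measure, and through the chain of both cross-construct
edges). `enumerate_mediation_paths()` lists **all** simple directed routes
excluding the single direct edge — the third, doubly-indirect route is kept
even though it is usually negligible, because only the full enumeration
makes the decomposition additive: the sum of all path products equals the
$(I-A)^{-1}$ total effect exactly, which the test suite asserts.

`decompose()` reports standardized direct, indirect (sum of path products)
and total effects with first-order delta-method SEs from the joint parameter
covariance. Percent-of-total columns and the $|indirect|/|direct|$ ratio
follow the published reporting convention: a derived quantity whose
denominator magnitude falls below 0.01 standardized units is flagged
`Div by 0` rather than reported. The 0.01 threshold is a reporting
convention reverse-engineered from the published table's flagging pattern
(a direct effect of −0.0040 is flagged there while 0.0172 is not); it is
configurable.

## Descriptives

`visit_summary()` gives per-visit means/SDs and contrasts of each follow-up
visit against baseline from a linear model with a participant-level random
intercept and visit as a categorical fixed effect (`nlme::lme`). When the
variance components are degenerate — e.g. an exactly deterministic shift —
the equivalent within-participant fixed-effects fit supplies the contrasts
and the method is recorded on the object.

`percent_change()` is deliberately the **mean of per-participant ratios**,
not the ratio of group means; the two differ whenever change correlates
with baseline, and the published change figures are consistent only with
per-participant averaging. `annualize()` divides by the nominal window in
years (120 months for the full study), which reproduces the published
annualized decline (−7.6% over ten years → −0.76%/yr); the median follow-up
(127 months) is intentionally not used. `lms_zscore()` implements
$z = ((X/M)^L - 1)/(LS)$ with the $\log$ continuity limit at $L = 0$;
reference LMS triplets are consumed as inputs, never estimated.

Age-progressed reference z-scores are out of scope: they require
age-specific reference parameters that are not published.

## The synthetic cohort generator

`synth_config()` + `simulate_cohort()` generate three-wave cohorts whose
generative structure is exactly the canonical CLPM, so the fitting engine is
correctly specified for its own generator — the property the calibration
and recovery tests exploit.

* **Marginal calibration.** Per-metric, per-visit means and SDs default to
  the cohort-scale reference values (leg LM 10.58 ± 1.54 kg at baseline
  declining to 9.77 ± 1.51 kg, leg BMD 1.403 ± 0.146 g/cm^2, and so on).
  Visit-level means are hit by centring the structural recursion and adding
  the target means; disturbance SDs are solved analytically, in causal
  order, so the implied marginal SDs match the targets exactly given the
  structural coefficients. An unattainable target (negative required
  disturbance variance) is an error naming the variable.
* **Structural defaults.** Contemporaneous coefficients (0.0316, −0.0108,
  0.0085 g/cm^2 per kg) and cross-lags (muscle→bone 0.0093, 0.0003;
  bone→muscle 0.0238, 0.0136) take the published unstandardized estimates.
  The autoregressions are 0.92 (muscle) and 0.95 (bone). The published raw
  bone autoregression is slightly above 1, but combined with
  near-constant BMD SDs across visits that leaves no room for a nonnegative
  disturbance variance in a homoscedastic Gaussian model (the arm pair is
  infeasible even at 0.98 once covariate effects contribute); 0.95 sits
  inside the published standardized range (0.90–1.04) and keeps every
  disturbance variance positive. This is the one structural default chosen
  by feasibility rather than copied from a published table.
* **Covariates.** Age is drawn from a normal distribution truncated at 40
  whose *truncated* moments are 53 ± 9 — the parent parameters are solved
  numerically, since a Normal(53, 9^2) truncated at 40 would have mean 54.4.
  Weight is BMI × (height/100)^2, so the BMI identity holds exactly.
  Covariate effect sizes are expressed per baseline SD of the target metric
  (the same vector gives comparable relative effects at leg and arm) and
  default to small, realistic values; walking amount and grip strength have
  no published distributions and their defaults (gamma and normal,
  respectively) are invented — flagged here deliberately.
* **Left/right limbs** are correlated replicates (disturbance correlation
  0.95); only the side-selection rule ever looks at the right side.
  Prosthesis/fracture flags are drawn once per side/limb (default 1%) and
  persist across visits. Dropout is whole-visit, missing completely at
  random (default 2% per follow-up visit), matching a complete-case
  analysis; informative dropout is out of scope. Hospitalization is
  generated at baseline only, matching the fitted model's baseline covariate
  block.
* **Heavier tails** are available through `disturbance_df` (scaled t) for
  robustness exercises; the default is Gaussian, which is what normal-theory
  ML assumes.

`implied_population_cov()` returns the exact population covariance implied
by a configuration via the same `implied_covariance()` code path the engine
uses, tying generator and engine together; the suite checks a 50,000-row
sample against it entry by entry.

What the generator does **not** emulate: DXA measurement drift or image
formation, nonlinear trajectories (three time points cannot identify them),
informative missingness, and real covariate dependence structures beyond
the height-weight coupling. Passing tests therefore demonstrate correctness
of the estimation machinery under its assumed model, not robustness to the
ways real cohort data violate those assumptions.

## The induced-association demonstration

Regressing an outcome's change on a predictor measured at the *start of the
change window* can manufacture an association where no lagged effect
exists: the predictor correlates with the outcome's starting value through
the contemporaneous path, and change mean-reverts. The demonstration config
(`induced_association_config()`) makes this airtight by construction: both
cross-lags zero, the only contemporaneous path at the mid visit, muscle
autoregression zero, bone autoregression 0.8. Then the population slope of
the baseline-timed predictor is exactly zero while the window-start
predictor's slope is $(\rho_B - 1)\beta_{V3}$ — both derivable from the
implied covariance and both verified against the fitted models. A
straightforward transplant of cohort-scale defaults cannot produce an exact
baseline null (earlier contemporaneous paths leak into the change through
the autoregressions), which is why the demonstration uses this purpose-built
configuration rather than the cohort defaults.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to give tight Monte-Carlo error
while keeping the suite fast: chi-square calibration uses 500 replicates of
n = 1000 under the no-covariate canonical model (df = 6); parameter
recovery uses 100 seeds of n = 10,000 with a three-covariate canonical
spec and pools 95% interval coverage across the nine structural labels;
the bootstrap check of the delta-method indirect-effect SE uses 300
resamples at n = 2000; the change-model coverage simulation uses 120
replicates of n = 1200; visit-contrast type-I error uses 200 replicates of
100 participants. Monte-Carlo tolerance bands are 3-sigma binomial or
moment bands throughout.

## Known limitations

* No latent variables, no FIML for missing data, no robust (sandwich) or
  categorical-data corrections: complete-case, observed-variable,
  normal-theory ML only.
* The contemporaneous muscle→bone orientation is a convention;
  within-visit associations are not causally identified.
* Appendicular BMD is the unweighted mean of leg and arm BMD; DXA area
  weights are not carried in the table format, so this is an approximation.
* The appendicular-mass doubling convention (`ALM = 2 × (leg + arm)` of the
  carried side) matches published baseline tables but real data with
  side substitutions may deviate at later visits.
* Delta-method SEs for standardized and decomposed effects are first-order;
  the suite checks them against a bootstrap at cohort-like sizes, where
  they agree to within 15%.
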