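---
title: "Augmented likelihood for interval-censored outcomes with error-prone auxiliary data"
author: "auglik"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmented likelihood for interval-censored outcomes with error-prone auxiliary data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auglik)
```

## The model

Consider a cohort followed over discrete visits at times
$\tau_0 = 0 < \tau_1 < \dots < \tau_J$, partitioning time into intervals
$(\tau_{j-1}, \tau_j]$ for $j = 1, \dots, J$ plus $(\tau_J, \infty)$ as
interval $J+1$.  A visit at exactly $\tau_l$ observes the event iff
$T \le \tau_l$ (the half-open convention; the boundary case never arises
with continuous event times but fixes the discretization).  The baseline
survival probabilities are $S_j = \Pr(T_0 > \tau_{j-1})$, so
$1 = S_1 > S_2 > \dots > S_{J+1} > 0$, and under proportional hazards a
subject with covariates $x$ has interval probabilities
$\theta_j(x) = S_j^{\eta} - S_{j+1}^{\eta}$ with $\eta = e^{x'\beta}$
(and $S_{J+2} \equiv 0$).

Two outcome measurements are available:

* **Auxiliary reports.** At each completed visit $l$ the subject reports
  a binary status $Y^*_{il}$ with sensitivity
  $Se = \Pr(Y^* = 1 \mid \text{event occurred by } \tau_l)$ and
  specificity $Sp = \Pr(Y^* = 0 \mid \text{event not yet occurred})$.
  Reporting stops at the first positive report.  Reports are assumed
  conditionally independent given the true event interval — a weak form
  of the usual assumption, because the series is truncated at the first
  positive.  The whole history enters the likelihood through
  $C_{ij} = \prod_l Se^{y}(1-Se)^{1-y}$ (for intervals $j \le l$) or
  $Sp^{1-y}(1-Sp)^{y}$ (for $j > l$); a subject with no reports has
  $C_{ij} \equiv 1$.

* **Gold standard.** A definitive status $\Delta_i$ is measured once, at
  visit $V_i$, and may be missing completely at random
  ($M_i = 1$ with rate MR).

The log-likelihood sums, per subject, the log of
$\sum_j C_{ij}\,\theta_j(x_i)$ over the intervals compatible with the
gold standard: $j \le V_i$ when $\Delta_i = 1$, $j > V_i$ when
$\Delta_i = 0$, and all $j$ when $M_i = 1$.  The observation process
(number and timing of reports, stopping at the first positive) is
assumed ignorable given the event time, so it contributes no likelihood
factor.  A subject whose history has zero probability under the supplied
$Se/Sp$ (possible only with perfect tests and contradictory data)
produces `-Inf` with the offending ids attached; `aug_fit()` refuses to
start rather than silently dropping such subjects.

## Estimation and numerical choices

* **Monotone baseline.** $S$ is optimized through cumulative log-hazard
  coordinates $a_1, \dots, a_J$ with
  $S_{j+1} = \exp\{-\sum_{k \le j} e^{a_k}\}$, which enforces strict
  monotonicity for any finite $a$ and leaves the problem unconstrained.
* **Optimizer.** BFGS on $(\beta, a)$ with the analytic score
  (`aug_score()`, verified against central finite differences to 1e-5);
  relative function tolerance 1e-12, and a convergence flag requiring
  the maximum absolute score component, scaled by the effective sample
  size, to be below 1e-6.
* **Starting values.** $\beta = 0$; equal baseline hazard increments
  matched to the observed gold-standard positivity fraction.  Fits are
  insensitive to the start (tested).
* **Covariance.** Inverse of the observed information, computed as
  central finite differences of the analytic score with step
  $10^{-5}(1 + |\psi_k|)$, mapped to the $(\beta, S)$ scale by the delta
  method.  Wald intervals use normal critical values; no profile
  likelihood is attempted.
* **Survey data.** The weighted likelihood $\sum_i w_i \ell_i$ is
  maximized; `binder_sandwich()` computes the Taylor-linearization
  variance $A^{-1} B A^{-1}$ with $A$ the numeric Jacobian of the
  weighted score total and $B$ the with-replacement between-PSU
  covariance $\sum_h \frac{n_h}{n_h-1}\sum_c (z_{hc}-\bar z_h)(\cdot)'$
  of PSU-summed weighted scores.  Strata with a single PSU raise an
  error by default; `lonely_psu = "center"` deviates the lone PSU total
  from the grand mean instead.
* **Comparator.** The no-auxiliary benchmark is a binary regression of
  $\Delta$ on $x$ with complementary log-log link (grouped-time
  proportional hazards) among subjects with an observed gold standard —
  a single intercept when assessment visits are common, per-visit
  intercepts otherwise — with model-based or design-based variance to
  match the proposed fit.

## Measurement error and multi-stage variance

When the exposure of interest $X$ is observed only through an error-prone
$X^*$ (linear measurement error) plus a calibration subset carrying a
reference measure $X^{**} = X + \epsilon$ with classical error,
`rc_fit()` chains four stages:

1. internal $Se/Sp$ estimation by cross-tabulating the auxiliary report
   made at the gold-standard visit against the gold standard (the
   "concurrent" default; conditional independence makes these
   proportions unbiased for the per-visit rates even though reporting
   stops at the first positive).  A "cumulative" option cross-tabulates
   the ever-reported-positive indicator instead; it mirrors how a status
   question is validated in practice but overstates per-visit
   sensitivity under this data-generating model, so it is not the
   default.
2. weighted least squares of $X^{**}$ on $(1, X^*, Z)$ — the calibration
   model.  Weights are used whenever a design is present; a flag
   disables this.
3. the outcome model (augmented likelihood or comparator) on the
   calibrated exposure $\hat X = \delta^{(0)} + \delta^{(1)}X^* +
   \delta^{(2)\prime}Z$.
4. a stacked M-estimation sandwich over the full parameter
   $(\delta, Se, Sp, \beta, a)$: $A$ is the numeric Jacobian of the
   stacked weighted estimating-equation total (block triangular — cross
   derivatives are computed numerically, no closed forms), and $B$ is
   the between-PSU covariance of the stacked per-subject contributions.
   The $Se/Sp$ stages enter as weighted binomial-proportion equations on
   the reference-positive and reference-negative margins, and only when
   the rates were estimated internally; with known rates and an
   error-free calibration stage the stacked variance collapses exactly
   to the plain design sandwich (tested to 1e-6).

Regression calibration is exact in linear models and approximate here;
it is reliable when the exposure effect is moderate and the event is
rare, which is the regime of the cohort-mimic scenario below.  The
stacked variance was additionally checked against a 500-resample
bootstrap of the full pipeline (agreement within 15%).

## What the simulators emulate

`scenario_config()` fixes each scenario's conditions; the defaults are
the study conditions, not tuning knobs.

* **Simple random samples** (`sim_cohort()`): one covariate,
  Gamma(0.2, 1) or Normal(0.2, 1); exponential event times with rate
  $\lambda_b e^{x\beta}$, $\beta = \log 1.5$ (or 0 for size checks);
  $\lambda_b \in \{0.023, 0.08, 0.17\}$ giving latent censoring of about
  0.90 / 0.70 / 0.48 at the year-4 gold standard; four annual reports at
  $Se = 0.80$, $Sp = 0.90$; gold-standard missingness 0, 0.2 or 0.4.
* **Stratified three-stage survey** (`sim_survey_cohort()`): four
  strata of 94 block groups each (the stage structure of the large area
  sample it mimics, with roughly ten-fold fewer persons per block
  group); 40% of block groups sampled per stratum, stratum-specific
  household fractions, and person fractions differing by an age-subgroup
  indicator, so weights vary; covariates Gamma(or Normal) with
  stratum-specific parameters perturbed per block group by
  U($\pm 0.15 \cdot$ parameter).  The superpopulation is regenerated
  each replication, so replications are independent draws from the
  unconditional design-and-outcome law and the estimand stays at the
  generating $\beta$.
* **Cohort mimic** (`sim_hchs_cohort()`): eight annual reports, gold
  standard at year 4, gold-standard missingness 0.29, report missingness
  0.20, and three covariates (log-scale dietary exposure, age, BMI)
  drawn per (sex, background) cell from multivariate normals whose
  moments are *synthetic stand-ins* — chosen to be realistic, not
  estimated from any cohort.  The error model is
  $X^* = 0.05 + 0.50X + 0.003\,Z_1 + 0.0009\,Z_2 + e$,
  $\sigma^2_e = 0.389$, with a calibration subset (450 of 12,987,
  scaled proportionally at smaller runs) carrying
  $X^{**} = X + \epsilon$, $\sigma^2_\epsilon = 0.019$.  The baseline
  rate is solved per cohort so the latent censoring fraction at year 4
  is 0.90.  Age and BMI enter the hazard standardized by fixed reference
  moments, keeping their log hazard ratios ($\log 0.7$, $\log 1.3$) on a
  per-SD scale.

Two generator decisions deserve emphasis.  First, the per-visit
reporting error rates in the cohort mimic are $Se = 0.61$, $Sp = 0.98$
(the prevalent-disease agreement of self-report against biomarker),
while the analysis estimates them internally at the gold-standard visit.
Second, report missingness in the cohort mimic is *monotone* — a
geometric loss-to-follow-up visit calibrated so the marginal per-visit
missingness is 0.20 — rather than independent per-visit deletion, which
the other scenarios use.  Attrition is the dominant missingness
mechanism in annual telephone follow-up, and the information content of
the late report stream (hence the efficiency gain over the no-auxiliary
estimator) depends materially on this choice.

What passing these simulations does **not** show: robustness to
misspecified $Se/Sp$ (supported but not part of the replicated tables),
informative report missingness, gold-standard missingness that is not
completely at random, household-level outcome correlation beyond shared
covariate shifts, or continuous-time interval censoring.  Time-varying
covariates and multiple gold-standard assessments are out of scope.

## Replication sizes and experiment design

`run_scenario()` derives one sub-seed per replication from a master
seed, so any subset of replications is reproducible and summaries are
order-invariant.  Failed replications (non-convergence, degenerate
samples) are recorded and excluded from medians, with the count
reported; a scenario with more than 5% failures is flagged.

`summarize_reps()` reports the median percent bias, the median estimated
SE (ASE), the empirical median absolute deviation scaled by 1.4826 (so
it estimates the sampling SD that the ASE targets), 95% Wald coverage at
the 1.96 critical value, the replication-wise median of
$\mathrm{Var}(\hat\beta_{\text{standard}}) /
\mathrm{Var}(\hat\beta_{\text{proposed}})$ (values above 1 favor the
augmented estimator), and, under the null, the empirical type I error.

The packaged acceptance runs use 4000 replications for each N = 1000
simple-random-sample setting (a median percent bias has Monte-Carlo SE
near 0.8 points there, which a 2-point bias bound requires), 1000 for
the size and normal-covariate checks, 150 at N = 10,000, 200 for the
survey scenario and 150 for the cohort mimic — sizes chosen so the whole
study runs in minutes on one CPU while keeping each summary's
Monte-Carlo error well inside the tolerance it is compared at.

## Known limitations

* The likelihood treats $Se$ and $Sp$ as constants across visits and
  subjects; visit- or covariate-dependent error rates would need a
  larger parameterization.  Reports made after the gold-standard visit
  are treated with the same $Se/Sp$, i.e. the reporting error is taken
  to be independent of the gold-standard outcome and its timing.
* The design-based sandwich is a with-replacement first-stage
  approximation: no finite-population corrections and no replicate
  weights.
* Only a single error-prone exposure is exercised ($p = 1$), though the
  calibration interfaces accept additional error-free covariates.
* Coverage of the design-based variance degrades in small samples with
  skewed covariates (visible in the survey scenario at N = 1000), a
  known property of linearization variances, not a defect of the
  implementation.
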