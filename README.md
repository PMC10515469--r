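# auglik

Augmented-likelihood estimation for interval-censored time-to-event
outcomes with error-prone auxiliary data.

## The problem

Large cohort studies often record a definitive ("gold standard") disease
status only once after baseline — a biomarker panel at a single follow-up
clinic visit — while cheap but error-prone indicators, such as annual
self-reports of a diagnosis, are collected at every contact.  Analyzing
only the gold standard throws away most of the follow-up information and
every subject who missed the clinic visit; analyzing the self-reports
alone imports their misclassification into the hazard estimates.

`auglik` implements a likelihood that uses both.  Follow-up is split into
discrete intervals at the visit times
`tau_0 = 0 < tau_1 < ... < tau_J`, with baseline survival
`S_j = P(T0 > tau_{j-1})` and interval probabilities
`theta_j = S_j - S_{j+1}` under a proportional hazards model
`S(t | x) = S0(t)^{exp(x'beta)}`.  Given known (or internally estimated)
sensitivity `Se` and specificity `Sp` of the auxiliary reports, and
conditional independence of reports given the true event interval, each
subject's report history enters through a per-interval factor

    C_ij = prod over observed reports (l, y) of
           Se^y (1-Se)^{1-y}      if the event interval j <= l
           Sp^{1-y} (1-Sp)^y      if the event interval j > l

and the subject's log-likelihood contribution is the log of
`sum_j C_ij theta_j(x_i)` over the intervals compatible with the gold
standard: intervals `1..V_i` for a validated positive at visit `V_i`,
`V_i+1..J+1` for a validated negative, and all intervals when the gold
standard is missing.  Maximization runs unconstrained via a cumulative
log-hazard parameterization of `S`; standard errors come from the inverse
observed information, from a design-based (Binder linearization) sandwich
for complex-survey samples, or from a stacked estimating-equation
sandwich when a regression-calibration stage corrects covariate
measurement error.

The package also provides the standard comparator (a binary
complementary log-log regression of the gold standard on covariates, the
grouped-time proportional hazards model), a simulation engine for
simple-random-sample, stratified three-stage survey, and large
cohort-mimicking scenarios, and an experiments layer that computes the
usual operating characteristics (median percent bias, median SE, scaled
MAD, coverage, relative efficiency, type I error).

## Worked example

Simulate a cohort of 2000 subjects with four annual self-reports
(Se = 0.8, Sp = 0.9), a gold standard at year 4 that is missing for 30%
of subjects, and a true hazard ratio of 1.5:

```r
library(auglik)
set.seed(2024)
cfg <- scenario_config(n = 2000, beta = log(1.5), lambda_b = 0.08, mr = 0.3)
sim <- sim_cohort(cfg)
d   <- aug_data(sim$subjects, sim$aux, sim$grid, misclass(0.8, 0.9))
aug_fit(d)
#> Augmented-likelihood proportional hazards fit
#>   n = 2000, J = 4, Se = 0.800, Sp = 0.900, logLik = -3403.592
#>   estimate     se      z  lower  upper     hr
#> x   0.4236 0.0765 5.5364 0.2736 0.5735 1.5274
#>   baseline survival: 1.000 0.920 0.844 0.784 0.718
cloglog_fit(d)
#> Grouped-time cloglog fit (no auxiliary data), n = 1406
#>   estimate     se     hr
#> x   0.4264 0.0877 1.5317
```

Both estimators recover the true log hazard ratio `log(1.5) = 0.405`,
but the augmented fit uses all 2000 subjects and their 6221 reports,
while the comparator drops the 594 subjects without a gold standard: the
ratio of estimated variances is `(0.0877/0.0765)^2 = 1.31`, a 31%
efficiency gain here.

For survey data, fit with `aug_fit_svy()` (weighted likelihood plus
between-PSU sandwich variance); for an error-prone exposure with a
calibration subset, use `rc_fit()`, which chains internal Se/Sp
estimation, regression calibration, the outcome fit, and the stacked
sandwich variance.  A command-line front end is installed at
`inst/cli/auglik.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","auglik.R",package="auglik"))')" \
  fit --subjects subjects.csv --aux aux_visits.csv \
  --se 0.8 --sp 0.9 --grid 0,1,2,3,4 --covariates x --out fit.csv
```

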