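---
title: "Population PK of total and unbound pamiparib: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK of total and unbound pamiparib: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamipk)
```

## The model

Pamiparib is a PARP1/2 inhibitor dosed orally at 60 mg twice daily.
`pamipk` models the total (`Cp`) and unbound (`Cu`) plasma
concentration-time data of a multiple-dose study jointly. The structural
model is a one-compartment model with first-order absorption (no lag) and
first-order elimination; with apparent parameters `Ka` (1/h), `V` (= V/F, L)
and `CL` (= CL/F, L/h), a dose `D` given at time `t_d` contributes

$$C_p(t) = \frac{D\,K_a}{V\,(K_a-K_e)}\left(e^{-K_e (t-t_d)} -
e^{-K_a (t-t_d)}\right), \qquad K_e = CL/V,$$

and doses superpose (linear kinetics). The unbound stream is linked by the
plasma unbound fraction, $C_u = C_p \times F_u$, so the two streams are two
observations of one kinetic process. One set of random effects per subject
drives both streams; $F_u$ is a population parameter with its own
interindividual variability (IIV).

**Individual model.** Parameters are log-normal:
$\psi_{i,p} = \theta_p\, e^{\beta_p' \mathrm{COV}_i}\, e^{\eta_{i,p}}$ with
independent $\eta_{i,p} \sim N(0, \omega_p^2)$ (diagonal covariance; no
correlations are estimated). Covariates enter uncentered through the
exponential form $\theta\,e^{\beta\,\mathrm{COV}}$, so typical values at the
population median covariates are, e.g.,
$TV_{CL} = \theta_{CL}\,e^{\beta_{AGE}\cdot 60}$. Power and linear forms
are available for covariate exploration; the exponential form is the
default throughout.

**Residual error.** Concentrations are modelled on the log scale (variance
stabilisation). The natural-scale combined error model $g = a + b f$
(additive coefficient `a` in mg/L, proportional coefficient `b`, exponent
fixed at 1) maps by the delta method to a log-scale standard deviation

$$\sigma(f) = a/f + b,$$

which is the form used identically by the trial generator and the fitter:
`log y = log f + sigma(f) eps`, `eps ~ N(0,1)`. This keeps `a` and `b`
interpretable on the combined-model scale while the likelihood is exactly
log-normal. Whether the proportional term should multiply the natural- or
log-scale prediction is not determined by the combined-model statement
alone; the delta-method convention above is this package's documented
choice. Each observation stream (total, unbound) carries its own `(a, b)`.

## Estimation: SAEM with MCMC conditional sampling

`saem_fit()` implements Stochastic Approximation EM:

* **Simulation step.** Each subject's random effects are updated by a
  componentwise random-walk Metropolis-Hastings kernel targeting
  $p(\eta_i \mid y_i, \theta)$; proposal scales adapt toward an acceptance
  rate of ~0.3, and chain state is carried across iterations (one chain per
  subject).
* **Stochastic approximation.** Sufficient statistics of the sampled
  log-parameters ($\phi_i = \log \psi_i$ and $\phi_i^2$) are smoothed with
  step size 1 for 300 exploratory iterations, then $k^{-0.7}$ for 200
  smoothing iterations (defaults; both configurable).
* **M-step.** Because the statistics live in log-parameter space, typical
  values and covariate coefficients update in closed form as a per-parameter
  linear regression of the smoothed $\phi$ on the covariate design, and the
  $\omega$ update is the corresponding residual second moment (with a mild
  variance-annealing floor during exploration to prevent early collapse).
  The residual coefficients `(a, b)` have no closed form under the
  log-scale combined model and are updated per stream by Nelder-Mead on the
  smoothed error objective. Fixed effects declared without IIV (omega set
  to 0) are updated by direct conditional maximisation of the observed-data
  likelihood, with a long polish after the final iteration; in the
  degenerate one-subject, zero-IIV case the fit therefore reduces to
  nonlinear least squares.

**Initial values** are data-driven but deterministic: `CL` from dose/AUC
(trapezoid over the observed totals), `V` from a 12-h half-life scale,
`Fu` from the median unbound/total ratio at matched times, omegas at 0.3,
`a = 0.1`, `b = 0.2`.

**Empirical Bayes estimates** are conditional *means* over 300-500
post-burn-in MCMC draws (not modes), mapped through the covariate model.

**Likelihood / OFV.** `log_likelihood_is()` estimates each subject's
marginal likelihood by importance sampling with a t(5) proposal centred at
the MCMC conditional mean and scale; the objective function value is
$-2\sum_i \log \hat L_i$ with a reported Monte-Carlo standard error. With
all omegas zero the likelihood is evaluated in closed form.

**Standard errors.** The observed Fisher information of the
importance-sampling log-likelihood is computed by central finite
differences on the transformed scale (log for positive parameters), with a
single proposal built at the estimate and common random numbers so the
Monte-Carlo noise cancels in the differences. A non-positive-definite
information matrix falls back to a pseudo-inverse with a warning. Because
the proposal is held at the estimate, curvature can be mildly
overestimated at finite sample size; the nonparametric bootstrap is the
package's cross-check for parameter uncertainty.

## Covariate model building

Screening (`gam_screen()`) is marginal: each candidate covariate is
regressed against the log empirical Bayes estimate of each parameter with
a penalised thin-plate spline (binary covariates as two-group terms),
continuous covariates centred at their median for screening only, and a
pair is carried forward when the term p-value is below 0.05. The inclusion
criterion (p-value rather than AIC) and the 0.05 level are configurable
choices; both are reported alongside AICs.

Stepwise covariate modelling (`scm()`) then adds candidates by full model
refits, accepting the largest OFV reduction above 3.875 (p < 0.05, kept at
the conventional printed value rather than the exact chi-square 3.841) and
backward-eliminates at 10.828 (p < 0.001). All OFVs in a comparison share
one importance-sampling seed and size so model differences are not
dominated by Monte-Carlo noise; ties break by larger reduction, then
alphabetically.

## Evaluation

* `gof_tables()` reports population/individual predictions and
  log-scale IWRES.
* `bootstrap()` resamples subjects with replacement (covariates attached),
  refits each replicate with a reduced iteration budget, and reports
  medians and percentile 95% CIs. Failed replicates are counted and
  excluded; more than 10% failures warns.
* `vpc()` simulates full study replicates (new etas and residuals) and
  compares observed 5/50/95th percentiles per nominal time with the
  simulated percentile ribbons and their confidence bands. The design is
  balanced, so bins are the exact nominal times. The reported coverage is
  the fraction of observations inside the median 5th-95th ribbon, expected
  near 90% for a well-specified model.
* `prediction_distribution()` simulates with residual error off
  (structural + IIV variability only). Its 95% band spans from the lower
  confidence bound of the 2.5th percentile to the upper confidence bound
  of the 97.5th percentile - the shaded-envelope convention of
  prediction-distribution plots - so coverage above 95% indicates no
  misspecification.

One quantile convention (median-unbiased, type 8) is used everywhere.

## Dosing-regimen simulation

`simulate_population()` draws virtual subjects (new etas; covariates from
the demographic sampler), and evaluates the unbound concentration over the
final dosing interval of a 5-day regimen on a 0.1 h grid using the
geometric-series steady-state closed form. Residual error is excluded:
exposure metrics are model-predicted concentrations. `Css_max` is the
per-subject maximum over the final interval, `Css_min` the trough at the
interval end, `Css_ave` the trapezoidal AUC over the interval divided by
the interval. Conversion to nM (molecular weight 298.3 g/mol) happens only
at this reporting boundary. Percentiles are pooled across all simulated
subjects of all datasets, which preserves the heavy lower tail that
dataset-level summaries would flatten. The target engagement ratio is the
unbound `Css_min` over the PARP IC50 (~1 nM), with 5 taken as the
threshold for full engagement; the headline output is the lowest dose
whose 5th-percentile ratio clears the threshold. `Css_ave` involves an
averaging convention that published tables do not pin down (interval
average vs whole-treatment average), so it is reported but not treated as
a reference-matching quantity.

## The synthetic trial generator

`generate_trial()` emulates the study design: 41 subjects, 60 mg every
12 h for 9 doses, both streams sampled at predose (encoded 0.05 h before
the 9th dose, strictly pre-dose) and 0.5, 1, 2, 4, 7, 24 h after the 9th
dose. Covariates are drawn from truncated log-normals whose
post-truncation median equals the published median (the truncation of an
asymmetric range would otherwise shift it) with the printed range as an
approximate central-95% span; binary covariates are Bernoulli at the
printed frequencies. Age and creatinine clearance are sampled
independently (no joint distribution is published); a correlation knob
exists for sensitivity work.

Residual-error magnitudes are not published, so the generator's defaults
are synthetic-only assumptions: `b = 0.2` on both streams and an additive
`a` that scales with the stream magnitude (`0.1` mg/L for total,
`0.1 x Fu ~ 0.004` mg/L for unbound), chosen so both streams carry
comparable, realistic log-scale scatter - a fixed 0.1 mg/L additive term
on a stream whose concentrations are two orders of magnitude smaller would
swamp it. What passing tests on these data show is self-consistency of the
pipeline (generation, estimation, selection, evaluation) under the stated
design; they cannot validate assay-specific error structure or covariate
joint distributions of real patients.

## Numerical choices and degenerate inputs

* `Ka = Ke` is handled by the analytic limit
  `D Ka (t - t_d) e^{-Ka (t-t_d)}/V` below a relative difference of 1e-6
  (continuous continuation).
* Simulated log-concentrations are clamped to ±600 before
  exponentiation so extreme random-effect draws cannot under/overflow.
* Omegas are floored at 1e-4 (scale of numerical noise), proposal scales
  at 1e-3.
* Steady-state evaluation uses the accumulation identity
  $(1 - e^{-k n \tau})/(1 - e^{-k\tau})$, verified against brute-force
  superposition to 1e-8 relative error.

## Problem sizes used by the test-suite

The checks in `tests/testthat` run the pipeline at desk scale: the full
study fit uses the default 300 + 200 iterations; replicate-based checks
use 150 + 100 iterations and 20 replicate trials for bias, 50 screening
replicates, 5 stepwise-selection replicates, 150 simulation replicates for
VPC/prediction-distribution coverage pooled over 4 generated studies, and
10 outer x 50 inner bootstrap replications. The dosing simulations use the
full 200 datasets x 41 subjects. These sizes are the package's choices for
a reproducible desk-scale validation; the corresponding full-scale
analyses (500 bootstrap replicates, 500 VPC simulations) use the same code
paths with larger arguments.

## Known limitations

* No lag time, transit absorption, multi-compartment disposition or
  nonlinear elimination - the selected structural model is the scope.
* No below-quantification-limit modelling; BLQ rows must be flagged
  `MDV = 1` or rejected.
* Random effects are independent; no interoccasion variability.
* Importance-sampling SEs can be anticonservative (see above); use the
  bootstrap for reporting.
* Simulated exposure percentiles propagate interindividual variability
  only, not parameter uncertainty.
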