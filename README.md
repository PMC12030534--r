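# pamipk

Population pharmacokinetics of **total and unbound pamiparib**, a PARP1/2
inhibitor dosed orally in glioblastoma patients. The package is a complete,
tested pipeline for the joint analysis of the two concentration streams:

* a **one-compartment** structural model with first-order absorption and
  elimination, the unbound stream linked by the plasma unbound fraction,
  `Cu = Cp × Fu`;
* log-normal interindividual variability on `Ka`, `V/F`, `CL/F` and `Fu`
  (individual model `ψ_i = θ · e^{β·COV_i} · e^{η_i}`,
  `η_i ~ N(0, ω²)`), and a combined residual-error model applied on the log
  scale, `σ(f) = a/f + b`, per stream;
* **SAEM** estimation with MCMC conditional sampling of the random effects,
  empirical Bayes estimates, an importance-sampling objective function
  (`OFV = −2 log L`), and finite-difference / bootstrap standard errors;
* covariate model building by **GAM screening** of empirical Bayes
  estimates followed by **stepwise covariate modelling**
  (forward ΔOFV > 3.875, backward ΔOFV > 10.828);
* model evaluation by goodness-of-fit tables, **nonparametric bootstrap**,
  **visual predictive checks** and prediction-distribution diagnostics;
* **dosing-regimen simulation**: steady-state unbound exposure percentiles
  in nM (`Css,max`, `Css,min`, `Css,ave`) and target-engagement ratios
  `Css,min / IC50` against the ~1 nM PARP IC50;
* a **synthetic trial generator** emulating the study design (41 subjects,
  60 mg twice daily for 9 doses, both streams sampled at predose and 0.5,
  1, 2, 4, 7, 24 h after the 9th dose, demographics at the published
  medians/ranges), so every stage is testable without clinical data.

Audience: pharmacometricians and statistical programmers who want a
self-contained, scriptable reimplementation of this class of analysis —
and a reproducible harness for method checks at desk scale.

## Worked example

```r
library(pamipk)

# a synthetic trial with the study's design and the final-model parameters
sc    <- scenario_library("paper-final")
trial <- generate_trial(sc$pop, sc$design, sc$spec, seed = 101)
trial
#> PK dataset: 41 subjects, 574 observation rows (total + unbound), 369 dosing events
#>   covariates: AGE, PCC, WT, BSA, SEX

# joint SAEM fit with creatinine clearance on V/F and age on CL/F
init <- initial_estimates(trial, betas = data.frame(
  parameter = c("V", "CL"), covariate = c("PCC", "AGE")))
fit <- saem_fit(trial, init = init, opts = saem_options(seed = 7))
fit
#> SAEM fit: 41 subjects, 500 iterations, OFV 471.4 (seed 7)
#> Population PK parameters (one-compartment oral, total + unbound)
#>   theta: Ka = 2.565, V = 10.87, CL = 9.089, Fu = 0.04336
#>   omega: Ka = 1.34, V = 0.428, CL = 0.459, Fu = 0.203
#>   beta : PCC on V = 0.01195 (exponential)
#>   beta : AGE on CL = -0.02122 (exponential)
#>   error[total]: a = 0.08312, b = 0.2255
#>   error[unbound]: a = 0.003675, b = 0.1985
```

`theta` are the fixed effects at covariate zero; the clinically meaningful
typical values apply the covariate model at the population medians
(age 60 years, creatinine clearance 111.5 mL/min):

```r
tv_cl <- fit$estimates$theta[["CL"]] * exp(fit$estimates$betas$beta[2] * 60)
signif(tv_cl, 3)          # 2.54 L/h  (generating value 2.59)
half_life(fit$estimates$theta[["V"]] * exp(fit$estimates$betas$beta[1] * 111.5),
          tv_cl)          # 11.2 h    (~12 h half-life, supporting BID dosing)
```

Steady-state unbound exposure under candidate regimens, and target
engagement against the PARP IC50:

```r
regs <- list(dosing_regimen(60, 12), dosing_regimen(20, 12), dosing_regimen(10, 12))
met  <- simulate_regimens(fit$estimates, regs, n_datasets = 200,
                          n_subjects = 41, seed = 1)
percentile_table(met)
#> Steady-state unbound exposure percentiles (nM):
#>    regimen Css_max_p5 Css_max_p50 Css_max_p95 Css_min_p5 Css_min_p50 Css_min_p95 ...
#>  60 mg BID      179.0       377.0         788      37.20       193.0       549.0
#>  20 mg BID       59.7       126.0         263      12.40        64.3       183.0
#>  10 mg BID       29.8        62.8         131       6.21        32.1        91.5

te_ratio_flag(percentile_table(met))
#> Lowest adequate dose (5th-percentile criterion): 10 mg BID
```

Each row pools 200 × 41 simulated subjects; `Css_min_p50` is the median
steady-state trough of unbound drug in nM after 5 days, and a regimen is
flagged adequate when even its 5th-percentile trough (fast-clearing
patients) is at least 5 × IC50. Under this fit, all three regimens clear
the threshold at the 5th percentile — dose reduction below 60 mg BID
retains full predicted target engagement.

## Layout

| Path | Contents |
|---|---|
| `R/pk_model.R` | structural/individual/error model, closed forms |
| `R/saem.R` | SAEM, MCMC conditional sampling, EBEs, OFV, standard errors |
| `R/covariates.R` | GAM screening, stepwise covariate modelling |
| `R/evaluation.R` | GoF, bootstrap, VPC, prediction distribution |
| `R/dosing_sim.R` | regimen simulation, steady-state metrics, target engagement |
| `R/synthetic_data.R` | trial designs, covariate sampler, scenario library |
| `R/data_io.R` | NONMEM-style CSV reader/writer, imputation, result files |
| `vignettes/pamipk-methods.Rmd` | model, assumptions, numerical choices |
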