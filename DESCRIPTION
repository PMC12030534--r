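Package: pamipk
Title: Population Pharmacokinetics of Total and Unbound Pamiparib
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint nonlinear mixed-effects modelling of total and unbound
    plasma concentrations of the PARP inhibitor pamiparib. Implements a
    one-compartment oral-absorption model linked across the two observation
    streams by the unbound fraction, SAEM estimation with MCMC conditional
    sampling, importance-sampling likelihood, GAM covariate screening and
    stepwise covariate modelling, nonparametric bootstrap and visual
    predictive checks, steady-state dosing-regimen simulation with
    target-engagement summaries, and a synthetic trial generator emulating
    a 41-patient twice-daily dosing study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
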