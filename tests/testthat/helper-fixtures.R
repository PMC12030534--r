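# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

# the emulated study: 41 subjects, 60 mg q12h x 9, final covariate model
fixture_trial <- function() {
  if (is.null(.fx$trial)) {
    sc <- scenario_library("paper-final")
    .fx$trial <- generate_trial(sc$pop, sc$design, sc$spec, seed = 101)
  }
  .fx$trial
}

# full-budget SAEM fit of the fixture trial with the generating covariate
# structure (betas estimated from 0)
fixture_fit <- function() {
  if (is.null(.fx$fit)) {
    d <- fixture_trial()
    init <- initial_estimates(
      d, betas = data.frame(parameter = c("V", "CL"),
                            covariate = c("PCC", "AGE")))
    .fx$fit <- saem_fit(d, init = init, opts = saem_options(seed = 7))
  }
  .fx$fit
}

# typical value at the study's median covariates from a fitted model
tv_at_medians <- function(pop, param, cov_name, cov_value) {
  b <- pop$betas$beta[pop$betas$parameter == param &
                        pop$betas$covariate == cov_name]
  pop$theta[[param]] * exp(b * cov_value)
}

reduced_opts <- function(seed, burn = 150, smooth = 100, transitions = 2) {
  saem_options(iter_burn = burn, iter_smooth = smooth,
               mcmc_transitions = transitions, ofv_samples = 0,
               ebe_draws = 0, seed = seed)
}
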