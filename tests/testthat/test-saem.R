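test_that("single-subject fit without IIV matches a nonlinear least-squares oracle", {
  pop1 <- pop_params(c(Ka = 1.2, V = 40, CL = 3, Fu = 0.05),
                     omegas = c(Ka = 0, V = 0, CL = 0, Fu = 0),
                     error = list(total = c(a = 1e-6, b = 0.01),
                                  unbound = c(a = 1e-6, b = 0.01)))
  des1 <- trial_design(n_subjects = 1,
                       sampling_offsets = c(0.5, 1, 2, 4, 7, 10, 24))
  d1 <- generate_trial(pop1, des1, covariate_spec(), seed = 9)
  init1 <- pop_params(c(Ka = 2, V = 30, CL = 2, Fu = 0.1),
                      omegas = c(Ka = 0, V = 0, CL = 0, Fu = 0),
                      error = list(total = c(a = 1e-6, b = 0.05),
                                   unbound = c(a = 1e-6, b = 0.05)))
  f1 <- saem_fit(d1, init = init1,
                 opts = saem_options(iter_burn = 200, iter_smooth = 200,
                                     ofv_samples = 0, ebe_draws = 0, seed = 3))
  # independent least-squares oracle on the same closed-form model
  obs1 <- d1$obs
  dose_tab <- data.frame(time = (0:8) * 12, amt = 60)
  ss_fn <- function(p) {
    cp <- concentration_total(c(Ka = exp(p[1]), V = exp(p[2]), CL = exp(p[3])),
                              dose_tab, obs1$TIME)
    f <- ifelse(obs1$stream == "unbound", cp * exp(p[4]), cp)
    sum((log(obs1$DV) - log(f))^2)
  }
  o <- optim(log(c(2, 30, 2, 0.1)), ss_fn, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  nls_est <- exp(o$par)
  expect_equal(unname(unlist(f1$estimates$theta)), unname(nls_est),
               tolerance = 0.01)
})

test_that("SAEM is bit-reproducible given the seed and errors on bad input", {
  d <- subset_subjects(fixture_trial(), 1:8)
  o <- reduced_opts(seed = 5, burn = 40, smooth = 30)
  f1 <- saem_fit(d, opts = o)
  f2 <- saem_fit(d, opts = o)
  expect_identical(flatten_params(f1$estimates), flatten_params(f2$estimates))
  expect_identical(f1$trace, f2$trace)
  expect_equal(nrow(f1$trace), 70)      # one trace row per iteration
  # empty / degenerate datasets are rejected
  expect_error(pk_dataset(d$obs[0, ], d$doses[0, ]), "dosing")
})

test_that("fitting the generating scenario recovers the fixed effects", {
  fit <- fixture_fit()
  est <- fit$estimates
  expect_equal(tv_at_medians(est, "CL", "AGE", 60), 2.59, tolerance = 0.15)
  expect_equal(tv_at_medians(est, "V", "PCC", 111.5), 42.8, tolerance = 0.2)
  expect_equal(est$theta[["Fu"]], 0.041, tolerance = 0.1)
  expect_true(is.finite(fit$ofv))
  expect_equal(nrow(fit$ebes), 41)      # one EBE record per subject
})

test_that("conditional sampler targets the prior without data and degenerates with omega", {
  pop <- scenario_library("no-covariates")$pop
  d <- generate_trial(pop, trial_design(n_subjects = 3), covariate_spec(),
                      seed = 6)
  # omega = 0 components never move
  pop0 <- pop
  pop0$omegas[["Ka"]] <- 0
  dr0 <- mcmc_conditional_sample(d, 1, pop0, n = 200, seed = 2)
  expect_true(all(dr0[, "Ka"] == 0))
  # rich low-noise subject: posterior mean recovers the generating eta
  pop_rich <- pop_params(pop$theta, omegas = c(Ka = 0.5, V = 0.3, CL = 0.3,
                                               Fu = 0.1),
                         error = list(total = c(a = 0.001, b = 0.02),
                                      unbound = c(a = 4e-5, b = 0.02)))
  des <- scenario_library("rich-design")$design
  des$n_subjects <- 1
  dr_trial <- generate_trial(pop_rich, des, covariate_spec(), seed = 8)
  true_eta <- attr(dr_trial, "truth")$etas[1, ]
  dr <- mcmc_conditional_sample(dr_trial, 1, pop_rich, n = 3000, seed = 3)
  expect_equal(colMeans(dr)[c("V", "CL", "Fu")],
               true_eta[c("V", "CL", "Fu")], tolerance = 0.1)
})

test_that("empirical Bayes estimates fall back to typical values when uninformed", {
  pop <- scenario_library("no-covariates")$pop
  d <- generate_trial(pop, trial_design(n_subjects = 4), covariate_spec(),
                      seed = 13)
  pop0 <- pop
  pop0$omegas[] <- 0
  e0 <- ebe(d, pop0, seed = 2, n_draws = 50, burn = 10)
  expect_equal(unname(as.matrix(e0[, c("Ka", "V", "CL", "Fu")])),
               matrix(rep(pop$theta, each = 4), 4, 4), tolerance = 1e-12)
})

test_that("importance-sampling OFV matches the closed form when omega = 0", {
  pop0 <- pop_params(c(Ka = 1.58, V = 42.8, CL = 2.59, Fu = 0.041),
                     omegas = c(Ka = 0, V = 0, CL = 0, Fu = 0),
                     error = list(total = c(a = 0.1, b = 0.2),
                                  unbound = c(a = 0.0041, b = 0.2)))
  sc <- scenario_library("no-covariates")
  d <- generate_trial(pop0, sc$design, sc$spec, seed = 5)
  res <- log_likelihood_is(d, pop0, M = 200, seed = 1)
  # independent closed-form Gaussian log-likelihood of the log-scale residuals
  dose_tab <- data.frame(time = (0:8) * 12, amt = 60)
  ll <- 0
  for (i in seq_len(nrow(d$obs))) {
    r <- d$obs[i, ]
    cp <- concentration_total(c(Ka = 1.58, V = 42.8, CL = 2.59), dose_tab,
                              r$TIME)
    f <- if (r$stream == "unbound") cp * 0.041 else cp
    e <- if (r$stream == "unbound") c(a = 0.0041, b = 0.2) else c(a = 0.1, b = 0.2)
    ll <- ll + dnorm(log(r$DV), log(f), residual_sd(f, e), log = TRUE)
  }
  expect_lt(abs(res$ofv - (-2 * ll)) / abs(2 * ll), 1e-6)
  expect_equal(res$se, 0)
})

test_that("Monte-Carlo error of the OFV shrinks like 1/sqrt(M)", {
  d <- subset_subjects(fixture_trial(), 1:10)
  pop <- scenario_library("paper-final")$pop
  se1 <- log_likelihood_is(d, pop, M = 300, seed = 4)$se
  se2 <- log_likelihood_is(d, pop, M = 1200, seed = 4)$se
  expect_equal(se1 / se2, 2, tolerance = 0.35)
})

test_that("the likelihood prefers the generating parameters over perturbed ones", {
  pop <- scenario_library("paper-final")$pop
  ord_ok <- vapply(1:5, function(s) {
    d <- generate_trial(pop, trial_design(n_subjects = 25), covariate_spec(),
                        seed = 400 + s)
    bad <- pop
    bad$theta[["CL"]] <- bad$theta[["CL"]] * 1.5
    ofv_true <- log_likelihood_is(d, pop, M = 400, seed = s)$ofv
    ofv_bad <- log_likelihood_is(d, bad, M = 400, seed = s)$ofv
    ofv_true < ofv_bad
  }, logical(1))
  expect_true(all(ord_ok))
})

test_that("standard errors are reported for estimated parameters only", {
  sc <- scenario_library("rich-design")
  des <- sc$design
  des$n_subjects <- 100
  d <- generate_trial(sc$pop, des, sc$spec, seed = 11)
  fit <- saem_fit(d, init = initial_estimates(d),
                  opts = reduced_opts(seed = 2, burn = 200, smooth = 150))
  rse <- standard_errors(fit, d, M = 200, seed = 5, h = 0.1)
  # precision of CL/F grows with a large richly sampled study
  expect_lt(rse[["theta.CL"]], 10)
  expect_true(all(rse >= 0))
  # a parameter fixed at omega = 0 is absent from the map
  init0 <- fit$estimates
  init0$omegas[["Fu"]] <- 0
  pk <- pamipk:::.pack_params(init0)
  expect_false("omega.Fu" %in% pk$name)
})
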