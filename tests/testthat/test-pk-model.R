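test_that("covariate model reproduces the typical-value parameterisation", {
  pop <- pop_params(
    theta = c(Ka = 1.58, V = 15, CL = 6.76, Fu = 0.041),
    betas = data.frame(parameter = c("V", "CL"), covariate = c("PCC", "AGE"),
                       beta = c(0.0094, -0.016)),
    omegas = c(Ka = 1.7, V = 0.39, CL = 0.47, Fu = 0.12))
  ind <- individual_parameters(pop, cov = c(PCC = 111.5, AGE = 60))
  # CL at the median age: 6.76 * exp(-0.016 * 60)
  expect_equal(ind$psi[["CL"]], 6.76 * exp(-0.96), tolerance = 1e-12)
  expect_equal(round(ind$psi[["CL"]], 2), 2.59)
  # V at the median creatinine clearance
  expect_equal(ind$psi[["V"]], 15 * exp(0.0094 * 111.5), tolerance = 1e-12)
  # identity: no betas, eta = 0
  pop0 <- pop_params(theta = c(Ka = 1, V = 2, CL = 3, Fu = 0.5))
  expect_equal(individual_parameters(pop0)$psi, pop0$theta)
  # missing covariate named in the error
  expect_error(individual_parameters(pop, cov = c(PCC = 111.5)), "AGE")
})

test_that("multiple-dose concentration obeys superposition, linearity and AUC", {
  psi <- c(Ka = 1.58, V = 44, CL = 2.59)
  doses <- data.frame(time = (0:8) * 12, amt = 60)
  # no absorption yet at t = 0
  expect_equal(concentration_total(psi, data.frame(time = 0, amt = 60), 0), 0)
  # AUC of a single dose = D / CL, by numeric quadrature
  auc <- integrate(function(t) concentration_total(
    psi, data.frame(time = 0, amt = 60), t), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(auc, 60 / 2.59, tolerance = 1e-6)
  # superposition: profile after 9 doses = sum of 9 single-dose profiles
  tt <- c(96.5, 98, 103, 120)
  multi <- concentration_total(psi, doses, tt)
  single <- Reduce(`+`, lapply(doses$time, function(td) {
    concentration_total(psi, data.frame(time = td, amt = 60), tt)
  }))
  expect_equal(multi, single, tolerance = 1e-12)
  # exact dose linearity
  expect_equal(concentration_total(psi, data.frame(time = doses$time, amt = 10), tt),
               multi / 6, tolerance = 1e-12)
  # Ka -> infinity converges to the oral bolus D/V exp(-Ke t)
  ke <- 2.59 / 44
  big_ka <- concentration_total(c(Ka = 5e4, V = 44, CL = 2.59),
                                data.frame(time = 0, amt = 60), c(1, 6, 12))
  expect_equal(big_ka, 60 / 44 * exp(-ke * c(1, 6, 12)), tolerance = 1e-3)
})

test_that("degenerate Ka = Ke limit is continuous", {
  d1 <- data.frame(time = 0, amt = 60)
  ke <- 2.59 / 44
  exact_limit <- concentration_total(c(Ka = ke, V = 44, CL = 2.59), d1, 5)
  nearby <- concentration_total(c(Ka = ke * (1 + 1e-5), V = 44, CL = 2.59), d1, 5)
  expect_equal(exact_limit, 60 * ke * 5 * exp(-ke * 5) / 44, tolerance = 1e-10)
  expect_equal(nearby, exact_limit, tolerance = 1e-4)
})

test_that("steady-state closed form matches brute-force superposition", {
  psi <- c(Ka = 1.58, V = 44, CL = 2.59)
  trough_cf <- steady_state_trough(psi, 60, 12)
  doses50 <- data.frame(time = (0:49) * 12, amt = 60)
  trough_bf <- concentration_total(psi, doses50, 50 * 12)
  expect_lt(abs(trough_cf - trough_bf) / trough_bf, 1e-8)
  expect_equal(trough_cf, 1.38, tolerance = 0.01)
  # matrix steady-state path agrees with the generic profile
  s <- c(0, 3, 6, 12)
  m <- pamipk:::ss_interval_conc(1.58, 44, 2.59, 60, 12, 9, s)
  doses9 <- data.frame(time = (0:8) * 12, amt = 60)
  expect_equal(as.vector(m), concentration_total(psi, doses9, 96 + s),
               tolerance = 1e-12)
})

test_that("unbound link and residual error model behave as specified", {
  expect_equal(concentration_unbound(2.0, 0.041), 0.082)
  expect_equal(concentration_unbound(5, 1), 5)
  expect_equal(concentration_unbound(0, 0.041), 0)
  expect_error(concentration_unbound(-1, 0.1))
  # sigma = a/f + b
  expect_equal(residual_sd(c(0.1, 1, 10), c(a = 0, b = 0.2)), rep(0.2, 3))
  expect_equal(residual_sd(1, c(a = 0.07, b = 0)), 0.07)
  expect_equal(residual_sd(0.5, c(a = 0.05, b = 0.2)), 0.3)
  expect_error(residual_sd(0, c(a = 0.1, b = 0.2)))
})

test_that("half-life and IIV conventions reproduce the reported quantities", {
  expect_equal(half_life(44, 2.59), log(2) * 44 / 2.59)
  expect_equal(half_life(44, 2.59), 11.8, tolerance = 0.01)
  expect_equal(half_life(3, 3), log(2))
  expect_equal(half_life(88, 2.59), 2 * half_life(44, 2.59))
  # omega SD -> CV% convention
  expect_equal(iiv_cv_percent(0), 0)
  expect_equal(iiv_cv_percent(0.47), 50, tolerance = 0.02)
  expect_equal(iiv_cv_percent(0.39), 41, tolerance = 0.02)
  expect_equal(iiv_cv_percent(1.7), 410, tolerance = 0.02)
  expect_equal(iiv_cv_percent(0.12), 12, tolerance = 0.02)
  # explained IIV
  expect_equal(explained_iiv_percent(53, 41), 100 * 12 / 53)
  expect_equal(explained_iiv_percent(53, 53), 0)
  expect_warning(neg <- explained_iiv_percent(40, 45), "increased")
  expect_lt(neg, 0)
})

test_that("unbound-scale parameters reproduce the total-scale kinetics", {
  dp <- derived_parameters(c(Ka = 1.58, V = 44, CL = 2.73, Fu = 0.042))
  expect_equal(dp$T_half, log(2) / dp$Ke)
  expect_gte(dp$V_u, 44)
  # unbound-scale V and CL agree with the independently reported unbound
  # parameterisation within 5%
  expect_equal(dp$V_u, 1017, tolerance = 0.05)
  expect_equal(dp$CL_u, 65.0, tolerance = 0.05)
})

test_that("pop_params validates its invariants", {
  expect_error(pop_params(c(Ka = 1, V = 2, CL = 3)), "theta")
  expect_error(pop_params(c(Ka = -1, V = 2, CL = 3, Fu = 0.5)))
  expect_error(pop_params(c(Ka = 1, V = 2, CL = 3, Fu = 1.5)), "Fu")
  expect_error(pop_params(c(Ka = 1, V = 2, CL = 3, Fu = 0.5),
                          omegas = c(CL = -0.1)))
  expect_error(pop_params(c(Ka = 1, V = 2, CL = 3, Fu = 0.5),
                          error = list(total = c(a = -1, b = 0.2))))
})
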