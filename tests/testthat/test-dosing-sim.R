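test_that("unit conversion to nM is exact", {
  expect_equal(mg_per_L_to_nM(0.2983, 298.3), 1000)
  expect_equal(mg_per_L_to_nM(0), 0)
  expect_equal(mg_per_L_to_nM(0.0566), 189.7, tolerance = 5e-4)
  expect_error(mg_per_L_to_nM(1, mw = 0))
})

test_that("steady-state metrics match closed-form oracles for the typical subject", {
  pop_fix <- pop_params(c(Ka = 1.58, V = 44, CL = 2.59, Fu = 0.041),
                        omegas = c(Ka = 0, V = 0, CL = 0, Fu = 0))
  sim <- simulate_population(pop_fix, dosing_regimen(60, 12, duration = 15),
                             n_datasets = 1, n_subjects = 1,
                             spec = c(AGE = 60, PCC = 111.5), seed = 1)
  m <- steady_state_metrics(sim)
  # trough: geometric-series closed form, converted to nM
  trough <- steady_state_trough(c(Ka = 1.58, V = 44, CL = 2.59), 60, 12)
  expect_equal(m$Css_min, mg_per_L_to_nM(trough * 0.041), tolerance = 1e-4)
  expect_equal(m$Css_min, 190, tolerance = 0.005)
  # Css_ave: trapezoid agrees with D Fu / (CL tau) within 0.5%
  expect_equal(m$Css_ave, mg_per_L_to_nM(60 * 0.041 / (2.59 * 12)),
               tolerance = 0.005)
  expect_true(m$Css_max >= m$Css_ave && m$Css_ave >= m$Css_min)
})

test_that("ten BID doses sit within 0.5% of the infinite-time trough", {
  psi <- c(Ka = 1.58, V = 42.8, CL = 2.59)
  t10 <- pamipk:::ss_interval_conc(1.58, 42.8, 2.59, 60, 12, 10, 12)[1, 1]
  tinf <- steady_state_trough(psi, 60, 12)
  expect_lt(abs(t10 - tinf) / tinf, 0.005)
})

test_that("profiles are exactly dose-proportional under a shared seed", {
  pop <- scenario_library("paper-final")$pop
  s60 <- simulate_population(pop, dosing_regimen(60, 12), n_datasets = 3,
                             n_subjects = 41, seed = 77)
  s10 <- simulate_population(pop, dosing_regimen(10, 12), n_datasets = 3,
                             n_subjects = 41, seed = 77)
  expect_equal(s10$conc_unbound, s60$conc_unbound / 6, tolerance = 1e-12)
  # fixed seed reproducibility
  s60b <- simulate_population(pop, dosing_regimen(60, 12), n_datasets = 3,
                              n_subjects = 41, seed = 77)
  expect_identical(s60$conc_unbound, s60b$conc_unbound)
})

test_that("QD troughs are below BID troughs for every subject at equal dose", {
  pop <- scenario_library("paper-final")$pop
  bid <- simulate_population(pop, dosing_regimen(60, 12), n_datasets = 2,
                             n_subjects = 41, seed = 5)
  qd <- simulate_population(pop, dosing_regimen(60, 24), n_datasets = 2,
                            n_subjects = 41, seed = 5)
  m_bid <- steady_state_metrics(bid)
  m_qd <- steady_state_metrics(qd)
  expect_true(all(m_qd$Css_min < m_bid$Css_min))
})

test_that("zero-IIV simulations collapse all percentiles to the typical subject", {
  pop0 <- pop_params(c(Ka = 1.58, V = 42.8, CL = 2.59, Fu = 0.041),
                     omegas = c(Ka = 0, V = 0, CL = 0, Fu = 0))
  sim <- simulate_population(pop0, dosing_regimen(60, 12), n_datasets = 5,
                             n_subjects = 41, spec = c(AGE = 60, PCC = 111.5),
                             seed = 2)
  met <- cbind(regimen = "60 mg BID", steady_state_metrics(sim))
  s <- percentile_table(met)
  expect_equal(s$table$Css_min_p5, s$table$Css_min_p95, tolerance = 1e-12)
  expect_equal(s$table$Css_max_p5, s$table$Css_max_p50, tolerance = 1e-12)
})

test_that("target-engagement report flags regimens against the IC50 threshold", {
  tab <- data.frame(regimen = c("10 mg BID", "20 mg BID", "60 mg BID"),
                    Css_min_p5 = c(3, 5, 16), Css_min_p50 = c(29, 58, 175),
                    Css_min_p95 = c(97, 194, 581))
  s <- structure(list(table = tab, probs = c(5, 50, 95)),
                 class = "simulation_summary")
  te <- te_ratio_flag(s, ic50 = 1, threshold = 5)
  expect_equal(te$table$ratio_p5, c(3, 5, 16))
  expect_equal(te$table$engaged_p5, c(FALSE, TRUE, TRUE))
  expect_equal(te$headline_regimen, "20 mg BID")
  # doubling the IC50 halves every ratio
  te2 <- te_ratio_flag(s, ic50 = 2, threshold = 5)
  expect_equal(te2$table$ratio_p50, te$table$ratio_p50 / 2)
  expect_error(te_ratio_flag(s, ic50 = 0), "ic50")
})

test_that("coarse grids and thin populations are flagged", {
  pop <- scenario_library("paper-final")$pop
  expect_warning(simulate_population(pop, dosing_regimen(60, 12),
                                     n_datasets = 1, n_subjects = 5,
                                     seed = 1, grid_by = 1), "grid")
  sim <- simulate_population(pop, dosing_regimen(60, 12), n_datasets = 1,
                             n_subjects = 50, seed = 1)
  met <- cbind(regimen = "60 mg BID", steady_state_metrics(sim))
  expect_warning(percentile_table(met), "fewer than 100")
})

test_that("profile ribbons cover the duration and preserve ordering", {
  pop <- scenario_library("paper-final")$pop
  sim <- simulate_population(pop, dosing_regimen(60, 12), n_datasets = 2,
                             n_subjects = 41, seed = 3)
  rib <- profile_percentiles(sim, grid_by = 2)
  expect_equal(range(rib$time), c(0, 120))
  expect_true(all(rib$p5 <= rib$p50 & rib$p50 <= rib$p95))
})
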