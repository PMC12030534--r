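test_that("IWRES is standard normal when evaluated at the generating truth", {
  sc <- scenario_library("paper-final")
  d <- generate_trial(sc$pop, sc$design, sc$spec, seed = 55)
  truth <- attr(d, "truth")
  ebes <- cbind(data.frame(ID = seq_len(41)), as.data.frame(truth$psi))
  g <- gof_tables(sc$pop, d, ebes = ebes)
  expect_true(all(is.finite(g$iwres)))
  expect_lt(abs(mean(g$iwres)), 0.1)
  expect_gt(sd(g$iwres), 0.85)
  expect_lt(sd(g$iwres), 1.15)
  expect_true(all(g$pred > 0) && all(g$ipred > 0))
  # zero residual error generator: IWRES identically 0 at the truth
  d0 <- generate_trial(sc$pop, sc$design, sc$spec, seed = 55,
                       residual_error = FALSE)
  ebes0 <- cbind(data.frame(ID = seq_len(41)),
                 as.data.frame(attr(d0, "truth")$psi))
  g0 <- gof_tables(sc$pop, d0, ebes = ebes0)
  expect_equal(max(abs(g0$iwres)), 0, tolerance = 1e-10)
})

test_that("bootstrap resampling honours its contract and reproducibility", {
  d <- subset_subjects(fixture_trial(), 1:10)
  init <- initial_estimates(d)
  o <- reduced_opts(seed = 1, burn = 40, smooth = 30, transitions = 1)
  b1 <- bootstrap(d, init, n_resamples = 5, seed = 9, opts = o)
  b2 <- bootstrap(d, init, n_resamples = 5, seed = 9, opts = o)
  expect_identical(b1$replicates, b2$replicates)      # same seed, same result
  expect_equal(nrow(b1$replicates) + b1$n_failed, 5)
  # resampled datasets keep the subject-slot count
  set.seed(9)
  take <- sample(d$ids, length(d$ids), replace = TRUE)
  rb <- pamipk:::.resample_dataset(d, take)
  expect_equal(n_subjects(rb), 10)
  expect_equal(nrow(rb$obs), nrow(d$obs))
  # percentile interval contains the median
  expect_true(all(b1$ci["2.5%", ] <= b1$median & b1$median <= b1$ci["97.5%", ]))
})

test_that("bootstrap medians approach the SAEM estimates on a low-noise study", {
  pop <- pop_params(c(Ka = 1.58, V = 42.8, CL = 2.59, Fu = 0.041),
                    omegas = c(Ka = 0.3, V = 0.15, CL = 0.15, Fu = 0.05),
                    error = list(total = c(a = 0.005, b = 0.03),
                                 unbound = c(a = 2e-4, b = 0.03)))
  d <- generate_trial(pop, trial_design(n_subjects = 30), covariate_spec(),
                      seed = 14)
  fit <- saem_fit(d, init = initial_estimates(d),
                  opts = reduced_opts(seed = 2, burn = 120, smooth = 80))
  b <- bootstrap(d, fit$estimates, n_resamples = 30, seed = 3,
                 opts = reduced_opts(seed = 1, burn = 60, smooth = 40,
                                     transitions = 1))
  for (p in c("theta.V", "theta.CL", "theta.Fu")) {
    gap <- abs(b$median[[p]] - flatten_params(fit$estimates)[[p]]) /
      flatten_params(fit$estimates)[[p]]
    expect_lt(gap, 0.05)
  }
})

test_that("VPC ribbons are monotone, reproducible and degenerate correctly", {
  sc <- scenario_library("paper-final")
  d <- generate_trial(sc$pop, sc$design, sc$spec, seed = 21)
  v1 <- vpc(d, sc$pop, n_sim = 100, seed = 4)
  v2 <- vpc(d, sc$pop, n_sim = 100, seed = 4)
  expect_identical(v1$bins, v2$bins)
  with(v1$bins, {
    expect_true(all(sim_p5 <= sim_p50 & sim_p50 <= sim_p95))
    expect_true(all(obs_p5 <= obs_p50 & obs_p50 <= obs_p95))
  })
  # zero IIV and zero residual error: all three percentile curves coincide
  pop0 <- pop_params(c(Ka = 1.58, V = 42.8, CL = 2.59, Fu = 0.041),
                     omegas = c(Ka = 0, V = 0, CL = 0, Fu = 0),
                     error = list(total = c(a = 0, b = 0),
                                  unbound = c(a = 0, b = 0)))
  d0 <- generate_trial(pop0, trial_design(n_subjects = 5), covariate_spec(),
                       seed = 3, residual_error = FALSE)
  v0 <- vpc(d0, pop0, n_sim = 20, seed = 1)
  expect_equal(v0$bins$sim_p5, v0$bins$sim_p95, tolerance = 1e-12)
  expect_equal(v0$bins$sim_p50, v0$bins$obs_p50, tolerance = 1e-12)
})

test_that("prediction-distribution bands exclude residual error by construction", {
  sc <- scenario_library("paper-final")
  d <- generate_trial(sc$pop, sc$design, sc$spec, seed = 23)
  p1 <- prediction_distribution(d, sc$pop, n_sim = 80, seed = 5)
  p2 <- prediction_distribution(d, sc$pop, n_sim = 80, seed = 5)
  expect_identical(p1$bins, p2$bins)
  expect_true(all(p1$bins$band_lo <= p1$bins$band_hi))
  # variance decomposition: switching residual error on widens the simulated
  # spread at every nominal time
  sim_on <- pamipk:::.simulate_replicates(d, sc$pop, 200, seed = 8,
                                          residual_error = TRUE)
  sim_off <- pamipk:::.simulate_replicates(d, sc$pop, 200, seed = 8,
                                           residual_error = FALSE)
  bin <- interaction(sim_on$ctx$time, sim_on$ctx$stream_idx, drop = TRUE)
  spread_by_bin <- function(x) {
    vapply(levels(bin), function(b) sd(log(x[bin == b, ])), numeric(1))
  }
  expect_true(all(spread_by_bin(sim_on$sims) > spread_by_bin(sim_off$sims)))
})
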