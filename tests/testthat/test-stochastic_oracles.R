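test_that("birth-death simulation reproduces Poisson stationary statistics", {
  bd <- simulate_birth_death(40, 1, sim_config(seed = 101, total_time = 2050,
                                               burn_in = 50,
                                               n_replicates = 40))
  expect_lt(abs(z_diff(bd$stationary_mean, bd$se$stationary_mean, 40)), 3)
  ## Fano factor 1 (Poisson): variance/mean
  expect_lt(abs(z_diff(bd$stationary_variance, bd$se$stationary_variance,
                       bd$stationary_mean, bd$se$stationary_mean)), 3)
  ## time-averaged variance: sigma^2 T/(m tau) = 2
  stat <- bd$time_avg_variance * bd$window / (bd$stationary_mean * 1)
  se <- bd$se$time_avg_variance * bd$window / bd$stationary_mean
  expect_lt(abs(z_diff(stat, se, 2)), 3)
})

test_that("simulation is reproducible bit-for-bit under a seed", {
  cfg <- sim_config(seed = 11, total_time = 300, burn_in = 20,
                    n_replicates = 5)
  a <- simulate_birth_death(20, 1, cfg)
  b <- simulate_birth_death(20, 1, cfg)
  expect_identical(a$window_means, b$window_means)
  expect_identical(a$stationary_mean, b$stationary_mean)
})

test_that("target-count statistics are independent of the transport-delay law", {
  cfg <- function(s) sim_config(seed = s, total_time = 2100, burn_in = 100,
                                n_replicates = 50)
  g1 <- simulate_generalized_dt(20, delay_deterministic(5), 1, cfg(201))
  g2 <- simulate_generalized_dt(20, delay_exponential(5), 1, cfg(202))
  g3 <- simulate_generalized_dt(20, delay_telegraph(4, gamma_entry = 2), 1,
                                cfg(203))
  for (g in list(g1, g2, g3)) {
    expect_lt(abs(z_diff(g$stationary_mean, g$se$stationary_mean, 20)), 3)
    expect_lt(abs(z_diff(g$fano, g$se$fano, 1)), 3)
  }
  expect_lt(abs(z_diff(g1$stationary_mean, g1$se$stationary_mean,
                       g2$stationary_mean, g2$se$stationary_mean)), 3)
  expect_lt(abs(z_diff(g1$fano, g1$se$fano, g2$fano, g2$se$fano)), 3)
})

test_that("arrivals at the target form a Poisson process at rate beta", {
  g <- simulate_generalized_dt(20, delay_deterministic(5), 1,
                               sim_config(seed = 204, total_time = 700,
                                          burn_in = 100, n_replicates = 10))
  gaps <- diff(g$arrival_times)
  expect_gt(length(gaps), 1e4)
  D <- suppressWarnings(ks.test(gaps, "pexp", 20))$statistic
  expect_lt(D, 1.63 / sqrt(length(gaps)))   # 1% critical value
})

test_that("negative delays are rejected", {
  expect_error(
    simulate_generalized_dt(5, function(n) rep(-1, n), 1,
                            sim_config(seed = 1, total_time = 50,
                                       burn_in = 10)),
    "negative")
})

test_that("routing by splitting probabilities reproduces the DT profile", {
  sh <- dt_shape(2, 8, 10)
  g <- gamma_profile(sh, 1:10)
  routing <- g / (2 * sum(g))               # pi_j over one side
  gr <- simulate_generalized_dt(50, delay_exponential(2), 1,
                                sim_config(seed = 205, total_time = 2100,
                                           burn_in = 100),
                                routing = routing)
  m_th <- mean_profile_dt(sh, dt_rates(50, 1, 100))
  z <- (gr$cell_means - m_th) / gr$cell_se
  expect_true(all(abs(z) < 3.5))
})

test_that("cytoneme transport integrator converges to the closed-form profile", {
  sh <- dt_shape(2, 8, 10)
  mp <- cytoneme_params_from_shape(sh, beta = 100, nu = 1)
  expect_equal(mp$phi, 2, tolerance = 1e-12)
  expect_equal(mp$kappa_a, sh$kappa_a, tolerance = 1e-12)
  ode <- integrate_cytoneme_ode(mp, grid_points = 100)
  m_th <- mean_profile_dt(sh, dt_rates(100, 1, 100))
  expect_true(ode$converged)
  expect_lt(max(abs(ode$m / m_th - 1)), 5e-3)
  expect_lt(ode$flux_error, 1e-3)
  ## grid convergence: doubling changes every cell by < 0.1%
  ode2 <- integrate_cytoneme_ode(mp, grid_points = 200)
  expect_lt(max(abs(ode2$m / ode$m - 1)), 1e-3)
})

test_that("SDC lattice simulation matches profile means and variances", {
  lh <- 2
  m_th <- mean_profile_sdc(sdc_params(100, lh^2, 1, 1), 3)
  tau_th <- correlation_time_sdc(lh, 1)
  sim <- simulate_sdc_lattice(beta = 100, D = lh^2, nu = 1, a = 1,
                              n_cells = 8, subcells_per_cell = 8,
                              config = sim_config(seed = 301,
                                                  total_time = 6100,
                                                  burn_in = 100,
                                                  n_replicates = 200),
                              probe_cells = 1:3)
  z_mean <- (sim$cells$mean - m_th) / sim$cells$mean_se
  expect_true(all(abs(z_mean) < 3))
  ## consecutive ratio e^{-2/lh}
  expect_equal(sim$cells$mean[3] / sim$cells$mean[2], exp(-2 / lh),
               tolerance = 0.05)
  var_th <- 2 * m_th * tau_th / sim$window
  z_var <- (sim$cells$time_avg_variance - var_th) / sim$cells$tav_se
  expect_true(all(abs(z_var) < 3))
  ## total count balances production
  expect_equal(sum(sim$all_cell_means), 100, tolerance = 0.05)
})

test_that("lattice boundary placement is enforced", {
  expect_error(
    simulate_sdc_lattice(10, 100, 1, 1, n_cells = 5, subcells_per_cell = 8,
                         config = sim_config(seed = 1, total_time = 100,
                                             burn_in = 10),
                         probe_cells = 3),
    "boundary")
})

test_that("concentration readout carries twice the arrival-count CV^2", {
  cv <- arrival_vs_concentration_cv(
    50, 1, sim_config(seed = 501, total_time = 50050, burn_in = 50,
                      n_replicates = 100))
  expect_lt(abs(z_diff(as.numeric(cv), attr(cv, "se"), 2)), 3)
  ## arrival readout itself: CV^2 = 1/(beta T)
  expect_equal(attr(cv, "cv2_arrival"), 1 / (50 * 500), tolerance = 0.35)
  ## invariance to the birth rate
  cv2 <- arrival_vs_concentration_cv(
    20, 1, sim_config(seed = 502, total_time = 50050, burn_in = 50,
                      n_replicates = 100))
  expect_lt(abs(z_diff(as.numeric(cv), attr(cv, "se"),
                       as.numeric(cv2), attr(cv2, "se"))), 3)
})
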