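test_that("Gamma_j limits: constant, exponential, and j = 0 identity", {
  ## strongly backward-biased: flat profile
  sh <- dt_shape(-10, 10, 100)
  g <- gamma_profile(sh, 1:100)
  expect_true(all(abs(g - 1) < 1e-4))
  ## strongly forward-biased: exponential with kappa_a = 0.1
  f10 <- solve_kappa(10, 1)                  # the lengthscale product at phi=10
  sh2 <- dt_shape(10, f10 / 0.1, 50)
  expect_equal(sh2$kappa_a, 0.1, tolerance = 1e-12)
  expect_equal(gamma_profile(sh2, 5), exp(-1), tolerance = 1e-3)
  ## j = 0 gives exactly 1 for any shape
  expect_identical(gamma_profile(sh, 0), 1)
  expect_identical(gamma_profile(sh2, 0), 1)
})

test_that("Gamma_j is in (0, 1], non-increasing, and matches the literal formula", {
  for (phi in c(-5, -0.5, 0.5, 2, 8)) {
    sh <- dt_shape(phi, 12, 200)
    g <- gamma_profile(sh, 1:200)
    expect_true(all(g > 0 & g <= 1))
    expect_true(all(diff(g) <= 1e-15))
    ## stable evaluation agrees with naive arithmetic where the latter works
    expect_equal(g, gamma_literal(phi, sh$kappa_a, 1:200), tolerance = 1e-12)
  }
  ## no overflow where the naive formula would blow up
  sh_big <- dt_shape(-600, 5, 50)
  expect_true(all(is.finite(gamma_profile(sh_big, 1:50))))
})

test_that("small-phi limit approaches the power law with d+ = phi/kappa", {
  ## just above the power-law switch, and with 2*N*kappa_a small so the
  ## exponential cutoff is negligible over the tested cells
  phi <- 2e-3
  lh <- 150
  sh <- dt_shape(phi, lh, 50)
  expect_false(sh$power_law)
  g <- gamma_profile(sh, 1:50)
  r <- phi / sh$kappa_a                      # d+/a implied by the kappa branch
  g_pl <- 1 / (1 + 2 * (1:50) / r)
  expect_equal(g, g_pl, tolerance = 2e-2)
})

test_that("closed-form lengthscale equals the quadrature of Gamma(j)", {
  ## the product reading of the lengthscale formula is exact for the
  ## integral definition; this is its validation
  for (phi in c(0.1, 0.5, 1, 2, 5, 10)) {
    ka <- solve_kappa(phi, 20)
    expect_equal(lengthscale_quadrature(phi, ka), 20, tolerance = 1e-6)
    expect_equal(lengthscale_dt(phi, ka), 20, tolerance = 1e-9)
  }
})

test_that("solve_kappa round-trips through lengthscale_dt", {
  set.seed(42)
  phi <- runif(40, -10, 10)
  phi <- phi[abs(phi) > 1e-3]
  lh <- exp(runif(length(phi), log(0.5), log(100)))
  ka <- solve_kappa(phi, lh)
  expect_true(all(sign(ka) == sign(phi)))
  expect_equal(lengthscale_dt(phi, ka), lh, tolerance = 1e-6)
  ## large-phi limit: kappa_a -> 1/lambda_hat
  expect_equal(solve_kappa(30, 10), 1 / 10, tolerance = 1e-6)
})

test_that("discrete-sum lengthscale carries a one-cell-radius offset", {
  ## for a near-pure exponential the discrete estimator equals
  ## 2/(1 - e^{-2/lh}) = lh + 1 + O(1/lh); the closed form is the
  ## integral value lh. Frozen from the sum oracle.
  for (lh in c(5, 20, 50)) {
    sh <- dt_shape(6, lh, 1000)
    expect_equal(lengthscale_dt_discrete(sh), 2 / (1 - exp(-2 / lh)),
                 tolerance = 2e-2)
    expect_equal(lengthscale_dt_discrete(sh), lh + 1, tolerance = 0.06)
  }
  ## at small phi the power-law core inflates the discrete estimate well
  ## beyond the integral value
  sh <- dt_shape(0.1, 5, 1000)
  expect_gt(lengthscale_dt_discrete(sh) / 5, 1.5)
})

test_that("power-law branch: solved d+/a reproduces the requested scale", {
  sh <- dt_shape(0, 20, 100)
  expect_true(sh$power_law)
  expect_equal(lengthscale_dt_discrete(sh), 20, tolerance = 1e-8)
  ## harmonic-sum feasibility bound
  expect_error(dt_shape(0, 10, 100), "harmonic-sum")
  ## continuity with the kappa branch at the threshold, matched on the
  ## discrete lengthscale definition (tolerance frozen from the oracle)
  shk <- dt_shape(1e-3, 20, 100)
  shp <- dt_shape(0, lengthscale_dt_discrete(shk), 100)
  expect_equal(gamma_profile(shp, 1:100), gamma_profile(shk, 1:100),
               tolerance = 2e-2)
})

test_that("mean DT profile conserves production exactly", {
  for (phi in c(-3, 0.5, 4)) {
    sh <- dt_shape(phi, 8, 60)
    r <- dt_rates(beta = 137, nu = 2.5, T = 50)
    m <- mean_profile_dt(sh, r)
    expect_equal(2 * sum(m), r$beta / r$nu, tolerance = 1e-12)
    expect_true(all(diff(m) <= 1e-15))
  }
})

test_that("DT precision: zero for flat profiles, nu-invariant at fixed beta*T", {
  sh <- dt_shape(-10, 10, 40)
  p <- precision_dt(sh, dt_rates(100, 1, 100))
  ## essentially flat profile: precision collapses to ~0 (a sloped
  ## profile at these rates has P^2 of order 1e-3)
  expect_true(all(p$p_squared < 1e-8))
  sh2 <- dt_shape(1.5, 10, 40)
  base <- precision_dt(sh2, dt_rates(100, 1, 100))
  for (nu in c(0.1, 10)) {
    p2 <- precision_dt(sh2, dt_rates(100, nu, 100))
    expect_equal(p2$p_squared, base$p_squared, tolerance = 1e-10)
  }
  expect_equal(base$tau, 1)
  expect_equal(base$delta_m,
               mean_profile_dt(sh2, dt_rates(100, 1, 100))[1:39] -
                 mean_profile_dt(sh2, dt_rates(100, 1, 100))[2:40])
})

test_that("single target cell per side receives half the production", {
  sh <- dt_shape(1, 5, 2)
  m <- mean_profile_dt(sh, dt_rates(10, 2, 100))
  expect_equal(2 * (m[1] + m[2]), 10 / 2, tolerance = 1e-12)
})

test_that("optimize_phi finds an interior optimum that dominates a dense grid", {
  res <- optimize_phi(100, 50, 10)
  expect_gt(res$phi_star, 0)
  ## dominance over a dense independent grid scan
  dense <- dt_p2_best_bruteforce(100, 10, 50,
                                 phi_grid = exp(seq(log(1e-3), log(30),
                                                    length.out = 2000)))
  expect_gte(res$p_squared_star, dense - 1e-9)
  ## positive optimum across lengthscales
  for (lh in c(1, 2, 5, 20, 50)) {
    r <- suppressWarnings(optimize_phi(100, 50, lh))
    expect_gt(r$phi_star, 0)
  }
  ## stability under grid refinement
  res2 <- optimize_phi(100, 50, 10, n_grid = 800)
  expect_equal(res2$phi_star, res$phi_star, tolerance = 1e-2)
})
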