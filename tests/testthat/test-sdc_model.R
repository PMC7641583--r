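test_that("mean concentration: source value, symmetry, conservation", {
  p <- sdc_params(beta = 80, D = 9, nu = 4, a = 1)
  lam <- sqrt(9 / 4)
  expect_equal(mean_concentration(p, 0), 80 / (2 * 4 * lam))
  xs <- c(0.3, 1.7, 5)
  expect_equal(mean_concentration(p, xs), mean_concentration(p, -xs))
  total <- integrate(function(x) mean_concentration(p, x), -Inf, 0,
                     rel.tol = 1e-10)$value +
    integrate(function(x) mean_concentration(p, x), 0, Inf,
              rel.tol = 1e-10)$value
  expect_equal(total, 80 / 4, tolerance = 1e-8)
})

test_that("cell-integrated SDC profile matches quadrature and tiles conservation", {
  p <- sdc_params(beta = 100, D = 25, nu = 1, a = 1)  # lambda_hat = 5
  m <- mean_profile_sdc(p, 10)
  m3_quad <- integrate(function(x) mean_concentration(p, x), 5, 7,
                       rel.tol = 1e-12)$value
  expect_equal(m[3], m3_quad, tolerance = 1e-10)
  ## constant consecutive ratio
  expect_equal(m[-1] / m[-10], rep(exp(-2 / 5), 9), tolerance = 1e-12)
  ## geometric tiling: 2 * sum_{j>=1} m_j + source interval = beta/nu
  lh <- p$lambda_hat
  m1 <- (100 / 1) * sinh(1 / lh) * exp(-2 / lh)
  tail_sum <- m1 / (1 - exp(-2 / lh))
  expect_equal(2 * tail_sum + (100 / 1) * (1 - exp(-1 / lh)), 100 / 1,
               tolerance = 1e-12)
})

test_that("correlation-time bracket: bounded, decreasing, correct limits", {
  lh <- exp(seq(log(0.01), log(1000), length.out = 400))
  B <- sdc_bracket(lh)
  expect_true(all(B > 0 & B < 1))
  ## saturates at 3/4 for tiny lengthscales, strictly decreasing beyond
  expect_true(all(diff(B) <= 0))
  expect_true(all(diff(sdc_bracket(exp(seq(log(0.5), log(100),
                                           length.out = 50)))) < 0))
  ## fast-diffusion limit lh * B -> 1
  expect_equal(1000 * sdc_bracket(1000), 1, tolerance = 2e-3)
  ## slow-diffusion limit B -> 3/4
  expect_equal(sdc_bracket(1e-3), 0.75, tolerance = 1e-3)
  ## agrees with the literal printed expression where that is computable
  lh_mid <- c(0.5, 1, 2, 10, 100)
  expect_equal(sdc_bracket(lh_mid), sdc_bracket_literal(lh_mid),
               tolerance = 1e-12)
  expect_equal(sdc_bracket(1), 0.5596485, tolerance = 1e-6)
  expect_equal(correlation_time_sdc(2, 4), sdc_bracket(2) / 4)
})

test_that("bracket matches the deterministic lattice covariance oracle", {
  ## regression-theorem solve on a fine subcell lattice, independent of
  ## the closed form; also confirms the 3/4 slow-diffusion limit
  for (lh in c(0.5, 1, 2, 10)) {
    tau_lat <- morphosense:::.sdc_lattice_tau_1d(lh, subcells = 32)
    expect_equal(tau_lat, sdc_bracket(lh), tolerance = 5e-3)
  }
  tau_small <- morphosense:::.sdc_lattice_tau_1d(0.05, subcells = 400,
                                                 jprobe = 1)
  expect_equal(tau_small, 0.75, tolerance = 2e-3)
})

test_that("fast-diffusion correlation time matches the hopping model", {
  for (lh in c(50, 200)) {
    h <- lh^2 / 4                        # D/(2a)^2 with a = nu = 1
    expect_equal(correlation_time_sdc(lh, 1), correlation_time_hopping(h, 1),
                 tolerance = 2e-2)
  }
})

test_that("SDC precision: constant steepness and nu-invariance", {
  lh <- 5
  base <- precision_sdc(sdc_params(100, lh^2, 1, 1), 20, T = 100)
  m <- mean_profile_sdc(sdc_params(100, lh^2, 1, 1), 20)
  expect_equal(base$delta_m / m[1:19], rep(1 - exp(-2 / lh), 19),
               tolerance = 1e-12)
  for (nu in c(0.1, 10)) {
    ## same beta*T and lambda_hat, different nu: D follows lambda_hat
    p <- sdc_params(100, lh^2 * nu, nu, 1)
    expect_equal(precision_sdc(p, 20, T = 100)$p_squared, base$p_squared,
                 tolerance = 1e-10)
  }
})

test_that("2D precision reduces to 1D when the transverse extent is one cell", {
  p2 <- sdc_params(1, 25, 1, 1, dim = 2)
  red <- precision_sdc_nd(p2, 10, T = 100, control = list(n_tcells = 1L))
  one <- precision_sdc(sdc_params(1, 25, 1, 1), 10, T = 100)
  expect_equal(red$p_squared, one$p_squared, tolerance = 1e-2)
})

test_that("transverse-mode engine agrees with a direct solve of the 2D lattice", {
  ## small system solved two ways: per-mode tridiagonal decomposition
  ## (package) versus one sparse solve of the full 2D generator (oracle)
  lh <- 2.5; S <- 4L; n_tcells <- 3L; N <- 4; jp <- 2
  pp <- precision_sdc_nd(sdc_params(1, lh^2, 1, 1, dim = 2), N, T = 100,
                         j = jp, control = list(subcells = S,
                                                n_tcells = n_tcells,
                                                margin_lambda = 3))
  ## direct construction of the full generator
  delta <- 2 / S
  h <- lh^2 / delta^2
  margin <- ceiling(max(3 * lh, 3) / delta)
  half <- (2 * N + 1) * S / 2 + margin
  nx <- 2 * half; My <- n_tcells * S; n <- nx * My
  idx <- function(x, y) (y - 1) * nx + x
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (y in 1:My) for (x in 1:nx) {
    i <- idx(x, y); d <- -1
    if (x > 1) { ti <- c(ti, idx(x - 1, y)); tj <- c(tj, i); tx <- c(tx, h); d <- d - h }
    if (x < nx) { ti <- c(ti, idx(x + 1, y)); tj <- c(tj, i); tx <- c(tx, h); d <- d - h }
    yp <- if (y == My) 1 else y + 1
    ym <- if (y == 1) My else y - 1
    ti <- c(ti, idx(x, yp), idx(x, ym)); tj <- c(tj, i, i); tx <- c(tx, h, h)
    d <- d - 2 * h
    ti <- c(ti, i); tj <- c(tj, i); tx <- c(tx, d)
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  b <- numeric(n)
  for (y in 1:My) b[c(idx(half, y), idx(half + 1, y))] <- 0.5 / S
  m <- as.numeric(Matrix::solve(A, -b))
  w <- numeric(n); wn <- numeric(n)
  for (y in 1:S) {
    w[idx((half + (2 * jp - 1) * S / 2 + 1):(half + (2 * jp + 1) * S / 2), y)] <- 1
    wn[idx((half + (2 * (jp + 1) - 1) * S / 2 + 1):
             (half + (2 * (jp + 1) + 1) * S / 2), y)] <- 1
  }
  z <- as.numeric(Matrix::solve(A, -(m * w)))
  s0 <- sum(w * z)
  dm <- sum(w * m) - sum(wn * m)
  p2_direct <- dm^2 * 100 / (2 * s0)
  expect_equal(pp$p_squared, p2_direct, tolerance = 1e-3)
  expect_equal(pp$tau, s0 / sum(w * m), tolerance = 1e-3)
})

test_that("transverse diffusion shortens the correlation time (2D, 3D)", {
  p2 <- sdc_params(1, 25, 1, 1, dim = 2)
  p3 <- sdc_params(1, 25, 1, 1, dim = 3)
  tau1 <- correlation_time_sdc(5, 1)
  tau2 <- precision_sdc_nd(p2, 8, T = 100, j = 3)$tau
  tau3 <- precision_sdc_nd(p3, 8, T = 100, j = 3)$tau
  expect_lt(tau2, tau1)
  expect_lt(tau3, tau2)
})

test_that("one-sided geometry doubles the mean profile only", {
  p <- sdc_params(50, 16, 1, 1)
  p1 <- sdc_params(50, 16, 1, 1, one_sided = TRUE)
  expect_equal(mean_profile_sdc(p1, 6), 2 * mean_profile_sdc(p, 6))
  expect_equal(mean_concentration(p1, 1.2), 2 * mean_concentration(p, 1.2))
})
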