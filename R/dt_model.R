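## Direct transport (cytoneme) model: steady-state profile, lengthscale,
## and readout precision.

## Below this |phi| the exponential/power-law closed forms degenerate and the
## profile is parametrised by d+/a instead of kappa*a.
.PHI_POWER_LAW <- 1e-3

#' Shape of a direct-transport morphogen profile
#'
#' Constructs the dimensionless description of a DT profile. The shape
#' parameter is \eqn{\phi = \log(d_-/d_+)}, where \eqn{d_\pm = v_\pm/\zeta_\pm}
#' are the mean distances a molecule runs forward/backward inside a cytoneme
#' before switching direction; \eqn{\kappa = 1/d_+ - 1/d_-} sets the profile
#' lengthscale. Given `phi` and the dimensionless lengthscale
#' `lambda_hat` (\eqn{\hat\lambda = \lambda/a}), `kappa_a` is derived with
#' [solve_kappa()] so that [lengthscale_dt()] round-trips.
#'
#' For \eqn{|\phi|} below `1e-3` the profile is a power law,
#' \eqn{\Gamma_j = (1 + 2ja/d_+)^{-1}}, and the free parameter \eqn{d_+/a}
#' is instead fixed by solving the discrete-sum lengthscale definition
#' (see [lengthscale_dt_discrete()]) for the requested `lambda_hat`.
#' That definition is bounded below by roughly \eqn{2\log N}, so short
#' power-law profiles on many cells are infeasible and raise an error.
#'
#' @param phi Real shape parameter; negative values give flat profiles,
#'   large positive values exponential ones.
#' @param lambda_hat Positive profile lengthscale in units of the cell
#'   radius \eqn{a}.
#' @param N Number of target cells on each side of the source (>= 2).
#' @return An object of class `dt_shape`: a list with `phi`, `lambda_hat`,
#'   `N`, `kappa_a`, and (power-law mode only) `d_plus_over_a`.
#' @seealso [gamma_profile()], [mean_profile_dt()], [precision_dt()]
#' @examples
#' sh <- dt_shape(phi = 1, lambda_hat = 10, N = 100)
#' sh$kappa_a
#' @export
dt_shape <- function(phi, lambda_hat, N) {
  stopifnot(is.numeric(phi), length(phi) == 1L, is.finite(phi))
  stopifnot(is.numeric(lambda_hat), length(lambda_hat) == 1L, lambda_hat > 0)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 2, N == round(N))
  power_law <- abs(phi) < .PHI_POWER_LAW
  if (power_law) {
    d_plus_over_a <- .solve_dplus_power_law(lambda_hat, N)
    kappa_a <- 0
  } else {
    d_plus_over_a <- NA_real_
    kappa_a <- solve_kappa(phi, lambda_hat)
  }
  structure(list(phi = phi, lambda_hat = lambda_hat, N = as.integer(N),
                 kappa_a = kappa_a, d_plus_over_a = d_plus_over_a,
                 power_law = power_law),
            class = "dt_shape")
}

#' @export
print.dt_shape <- function(x, ...) {
  cat("DT profile shape\n")
  cat(sprintf("  phi        = %g\n  lambda_hat = %g\n  N          = %d\n",
              x$phi, x$lambda_hat, x$N))
  if (x$power_law)
    cat(sprintf("  mode: power law, d+/a = %g\n", x$d_plus_over_a))
  else
    cat(sprintf("  kappa*a    = %g\n", x$kappa_a))
  invisible(x)
}

#' Production/degradation rates and integration time for the DT model
#'
#' @param beta Morphogen production rate of the source cell (molecules per
#'   unit time).
#' @param nu Degradation rate inside target cells (1/time).
#' @param T Integration (time-averaging) window of the readout. The
#'   precision formulas assume `T * nu >> 1`; a warning is issued when
#'   `T * nu < 10`.
#' @return An object of class `dt_rates`.
#' @export
dt_rates <- function(beta, nu, T) {
  stopifnot(beta > 0, nu > 0, T > 0)
  if (T * nu < 10)
    warning("T * nu < 10: the time-averaging assumption T >> 1/nu is violated")
  structure(list(beta = beta, nu = nu, T = T), class = "dt_rates")
}

## product (e^|phi| - 1) * (|phi| - log(e^|phi| - 1)), numerically stable.
.lengthscale_product <- function(phi) {
  p <- abs(phi)
  out <- numeric(length(p))
  big <- p > 30
  ## |phi| - log(e^|phi| - 1) = -log1p(-e^{-|phi|})
  out[!big] <- expm1(p[!big]) * (-log1p(-exp(-p[!big])))
  ## u = e^{-p} small: product = (1-u)(1 + u/2 + u^2/3 + ...)
  u <- exp(-p[big])
  out[big] <- (1 - u) * (1 + u / 2 + u^2 / 3)
  out
}

#' Eliminate the run-length parameter: solve for kappa*a
#'
#' Inverts the closed-form lengthscale relation, returning
#' \eqn{\kappa a = \mathrm{sign}(\phi)\,(e^{|\phi|}-1)(|\phi| -
#' \log(e^{|\phi|}-1))/\hat\lambda}. Round-trips through
#' [lengthscale_dt()] to within 1e-6 relative. `phi = 0` returns 0
#' (power-law mode; \eqn{d_+/a} is then solved separately, see
#' [dt_shape()]).
#'
#' @param phi Shape parameter (may be vectorised).
#' @param lambda_hat Positive dimensionless lengthscale.
#' @return kappa*a, with the sign of `phi`.
#' @export
solve_kappa <- function(phi, lambda_hat) {
  stopifnot(all(lambda_hat > 0))
  sign(phi) * .lengthscale_product(phi) / lambda_hat
}

#' Closed-form DT profile lengthscale
#'
#' The profile lengthscale of the DT model in units of the cell radius:
#' \eqn{\hat\lambda = (e^{|\phi|}-1)(|\phi|-\log(e^{|\phi|}-1))/|\kappa a|}.
#' This is the integral approximation of the discrete per-cell sum (exact
#' quadrature of \eqn{\Gamma(j)} over \eqn{j}, valid for \eqn{N \gg 1});
#' the exact discrete definition is exposed as
#' [lengthscale_dt_discrete()]. In the strongly forward-biased limit
#' \eqn{\phi \to \infty} it reduces to \eqn{1/|\kappa a|}.
#'
#' @param phi Shape parameter, non-zero.
#' @param kappa_a kappa*a, same sign as `phi`, non-zero.
#' @return Positive lengthscale \eqn{\hat\lambda}.
#' @export
lengthscale_dt <- function(phi, kappa_a) {
  if (any(phi == 0) || any(kappa_a == 0))
    stop("phi = 0 or kappa_a = 0: use the power-law parametrisation (dt_shape)")
  if (any(sign(phi) != sign(kappa_a)))
    stop("kappa_a must have the sign of phi")
  .lengthscale_product(phi) / abs(kappa_a)
}

#' Discrete-sum DT profile lengthscale
#'
#' The exact per-cell definition of the profile lengthscale,
#' \eqn{\hat\lambda_{disc} = 2(\sum_{j=1}^N \Gamma_j - \Gamma_N) /
#' (\Gamma_1 - \Gamma_N)} (the factor 2 converts cell indices to units of
#' `a`; cells sit at \eqn{x = 2ja}). For a geometric profile this
#' estimator equals \eqn{2/(1-e^{-2/\hat\lambda})}, i.e. it exceeds the
#' closed-form (integral) lengthscale by approximately one cell radius
#' even in the pure-exponential limit; the gap grows for small
#' \eqn{|\phi|}, where the power-law core decays within a few cells.
#'
#' @param shape A [dt_shape()] object.
#' @return Positive lengthscale estimate.
#' @export
lengthscale_dt_discrete <- function(shape) {
  g <- gamma_profile(shape, seq_len(shape$N))
  2 * (sum(g) - g[shape$N]) / (g[1] - g[shape$N])
}

## raw Gamma_j evaluation, vectorised over j; log/expm1-domain, no overflow.
.gamma_dt <- function(phi, kappa_a, j, d_plus_over_a = NA_real_) {
  if (abs(phi) < .PHI_POWER_LAW) {
    if (!is.finite(d_plus_over_a))
      stop("power-law mode requires d_plus_over_a")
    return(1 / (1 + 2 * j / d_plus_over_a))
  }
  out <- numeric(length(j))
  z <- j == 0
  out[z] <- 1
  j <- j[!z]
  if (phi > 0) {
    ## e^{-2 j ka} * (1 - e^{-phi}) / (1 - e^{-(phi + 2 j ka)})
    val <- exp(-2 * j * kappa_a) * expm1(-phi) / expm1(-(phi + 2 * j * kappa_a))
  } else {
    ## (1 - e^{phi}) / (1 - e^{phi + 2 j ka}); phi, kappa_a < 0
    val <- expm1(phi) / expm1(phi + 2 * j * kappa_a)
  }
  out[!z] <- val
  out
}

#' Per-cell transport factor of the DT model
#'
#' \eqn{\gamma \Gamma_j} is the effective rate at which morphogen is
#' delivered to target cell \eqn{j}:
#' \eqn{\Gamma_j = e^{-2j\kappa a}(1-e^{-\phi})/(1-e^{-\phi-2j\kappa a})}.
#' \eqn{\Gamma_j \in (0, 1]} and is non-increasing in \eqn{j}. Limits:
#' constant (\eqn{\Gamma_j \to 1}) for \eqn{\phi \ll -1}, exponential
#' (\eqn{e^{-2j\kappa a}}) for \eqn{\phi \gg 1}, power law
#' (\eqn{(1+2ja/d_+)^{-1}}) for \eqn{|\phi| \ll 1}. Evaluation is done in
#' the expm1/log domain so large \eqn{|\phi|} or \eqn{j\kappa a} never
#' overflow.
#'
#' @param shape A [dt_shape()] object.
#' @param j Cell index (vectorised); `j = 0` returns 1 (algebraic
#'   identity).
#' @return Numeric vector of \eqn{\Gamma_j}.
#' @export
gamma_profile <- function(shape, j) {
  stopifnot(inherits(shape, "dt_shape"), all(j >= 0), all(j == round(j)))
  .gamma_dt(shape$phi, shape$kappa_a, j, shape$d_plus_over_a)
}

## discrete lengthscale of the pure power-law family, and its inversion.
.power_law_lengthscale <- function(r, N) {
  j <- seq_len(N)
  g <- 1 / (1 + 2 * j / r)
  2 * (sum(g) - g[N]) / (g[1] - g[N])
}

.solve_dplus_power_law <- function(lambda_hat, N) {
  j <- seq_len(N)
  ## r -> 0 limit of the discrete lengthscale: 2*(H_N - 1/N)/(1 - 1/N)
  lh_min <- 2 * (sum(1 / j) - 1 / N) / (1 - 1 / N)
  if (lambda_hat <= lh_min * (1 + 1e-10))
    stop(sprintf(paste0("power-law profiles on N = %d cells cannot be shorter ",
                        "than lambda_hat = %.4g (harmonic-sum bound); ",
                        "requested %.4g"), N, lh_min, lambda_hat))
  hi <- max(4, 2 * lambda_hat)
  while (.power_law_lengthscale(hi, N) < lambda_hat) hi <- hi * 4
  uniroot(function(r) .power_law_lengthscale(r, N) - lambda_hat,
          lower = 1e-12, upper = hi, tol = 1e-10)$root
}

#' Steady-state mean DT profile
#'
#' \eqn{m_j = \beta \Gamma_j / (2\nu \sum_{k=1}^N \Gamma_k)} for
#' \eqn{j = 1..N}. Production balances degradation exactly: summed over
#' all \eqn{2N} target cells, \eqn{2\sum_j m_j = \beta/\nu}.
#'
#' @param shape A [dt_shape()] object.
#' @param rates A [dt_rates()] object.
#' @return Numeric vector of mean molecule counts, one per cell
#'   \eqn{j = 1..N} on one side of the source.
#' @export
mean_profile_dt <- function(shape, rates) {
  stopifnot(inherits(shape, "dt_shape"), inherits(rates, "dt_rates"))
  g <- gamma_profile(shape, seq_len(shape$N))
  rates$beta * g / (2 * rates$nu * sum(g))
}

#' Readout precision of the DT model
#'
#' \eqn{P_j^2 = (m_j T / 2\tau)(\Delta m_j/m_j)^2} with correlation time
#' \eqn{\tau = 1/\nu} and \eqn{\Delta m_j = m_j - m_{j+1}}, defined for
#' \eqn{j = 1..N-1}. Because the arrival of molecules at a target cell is
#' a Poisson process whatever the transport kinetics, the count variance
#' is that of a birth-death process (\eqn{\sigma_j^2 = 2 m_j \tau / T})
#' and the transport mechanism enters only through \eqn{m_j}. At fixed
#' \eqn{\beta T}, \eqn{P_j^2} is independent of \eqn{\nu}.
#'
#' @inheritParams mean_profile_dt
#' @return An object of class `ms_precision`: list with `p_squared`
#'   (length N-1), `tau`, `delta_m`, and `j`.
#' @export
precision_dt <- function(shape, rates) {
  m <- mean_profile_dt(shape, rates)
  .assemble_precision(m, tau = 1 / rates$nu, T = rates$T)
}

## shared P^2 assembly for both models
.assemble_precision <- function(m, tau, T) {
  N <- length(m)
  j <- seq_len(N - 1)
  dm <- m[j] - m[j + 1]
  p2 <- numeric(N - 1)
  pos <- m[j] > 0
  if (!all(pos)) {
    warning("zero mean count encountered; P^2 set to 0 for those cells")
  }
  p2[pos] <- (m[j][pos] * T / (2 * tau)) * (dm[pos] / m[j][pos])^2
  structure(list(p_squared = p2, tau = tau, delta_m = dm, j = j),
            class = "ms_precision")
}

#' @export
print.ms_precision <- function(x, ...) {
  cat(sprintf("readout precision for %d cell pairs; tau = %g\n",
              length(x$p_squared), x$tau))
  print(head(data.frame(j = x$j, delta_m = x$delta_m,
                        p_squared = x$p_squared), 10))
  if (length(x$j) > 10) cat("...\n")
  invisible(x)
}

#' Optimal DT shape parameter
#'
#' Finds the \eqn{\phi > 0} that maximises the DT precision \eqn{P_j^2}
#' at fixed lengthscale (with \eqn{\beta = T = \nu = 1}, which only
#' rescales the objective). An exponential profile (\eqn{\phi \gg 1}) has
#' constant steepness but small amplitude, a power-law profile
#' (\eqn{\phi \ll 1}) has low steepness but a large amplitude; the
#' optimum lies in between. Search: 400-point log grid on
#' \eqn{[10^{-3}, 30]} followed by golden-section refinement to 1e-6 in
#' \eqn{\phi}; ties break toward smaller \eqn{\phi}.
#'
#' @param N Cells per side.
#' @param j Cell index, `1 <= j <= N-1`.
#' @param lambda_hat Profile lengthscale (units of `a`).
#' @param window Search window for `phi` (positive).
#' @param n_grid Number of initial log-spaced grid points.
#' @return List with `phi_star` and `p_squared_star`.
#' @export
optimize_phi <- function(N, j, lambda_hat, window = c(1e-3, 30),
                         n_grid = 400) {
  stopifnot(j >= 1, j <= N - 1)
  res <- .dt_opt_phi(N, lambda_hat, j_set = j, window = window,
                     n_grid = n_grid)
  list(phi_star = res$phi_star[1], p_squared_star = res$p_squared_star[1])
}

## P^2_j for all requested j at the given phi values (beta = T = nu = 1).
## phi: vector (one value per column); returns matrix |j_set| x |phi|.
.dt_p2_matrix <- function(N, lambda_hat, phi, j_set) {
  ka <- .lengthscale_product(phi) / lambda_hat        # phi > 0 assumed
  jj <- seq_len(N)
  ## G[j, p]
  E <- exp(outer(jj, -2 * ka))                        # e^{-2 j ka_p}
  num <- matrix(expm1(-phi), nrow = N, ncol = length(phi), byrow = TRUE)
  den <- expm1(outer(-2 * jj, ka) - matrix(phi, N, length(phi), byrow = TRUE))
  G <- E * num / den
  S <- colSums(G)
  M <- sweep(G, 2, 2 * S, "/")                        # m_j at beta = nu = 1
  dm <- M[j_set, , drop = FALSE] - M[j_set + 1, , drop = FALSE]
  dm^2 / (2 * M[j_set, , drop = FALSE])
}

## vectorised-over-j optimiser: grid scan + per-j golden-section refinement.
.dt_opt_phi <- function(N, lambda_hat, j_set = seq_len(N - 1),
                        window = c(1e-3, 30), n_grid = 400, tol = 1e-6,
                        warn_boundary = TRUE) {
  grid <- exp(seq(log(window[1]), log(window[2]), length.out = n_grid))
  P2 <- .dt_p2_matrix(N, lambda_hat, grid, j_set)
  imax <- apply(P2, 1, which.max)                     # first max: smaller phi
  boundary <- imax == 1L | imax == n_grid
  if (any(boundary) && warn_boundary)
    warning("phi* at the search-window boundary for some cells; ",
            "grid argmax returned without refinement")
  lo <- grid[pmax(imax - 1L, 1L)]
  hi <- grid[pmin(imax + 1L, n_grid)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f_at <- function(x) {
    ## per-j distinct phi: evaluate each j at its own phi
    vapply(seq_along(j_set), function(i)
      .dt_p2_matrix(N, lambda_hat, x[i], j_set[i])[1, 1], numeric(1))
  }
  f1 <- f_at(x1); f2 <- f_at(x2)
  while (max(hi - lo) > tol) {
    take1 <- f1 >= f2                                 # ties -> smaller phi
    hi[take1] <- x2[take1]
    x2[take1] <- x1[take1]
    f2[take1] <- f1[take1]
    x1[take1] <- hi[take1] - gr * (hi[take1] - lo[take1])
    f1[take1] <- f_at(x1)[take1]
    lo[!take1] <- x1[!take1]
    x1[!take1] <- x2[!take1]
    f1[!take1] <- f2[!take1]
    x2[!take1] <- lo[!take1] + gr * (hi[!take1] - lo[!take1])
    f2[!take1] <- f_at(x2)[!take1]
  }
  phi_star <- (lo + hi) / 2
  phi_star[boundary] <- grid[imax[boundary]]
  p2_star <- f_at(phi_star)
  gridmax <- P2[cbind(seq_along(j_set), imax)]
  worse <- p2_star < gridmax
  phi_star[worse] <- grid[imax[worse]]
  p2_star[worse] <- gridmax[worse]
  list(phi_star = phi_star, p_squared_star = p2_star, j = j_set)
}
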