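## Synthetic-data generators and brute-force oracles: exact event-driven
## (Gillespie) simulators, an independent-molecule sampler for arbitrary
## transport-delay laws, and a deterministic upwind integrator for the
## cytoneme transport equations. Every closed form in the package is
## validated against one of these.

#' Simulation configuration
#'
#' All simulators carve `n_replicates` non-overlapping windows of equal
#' length from a single trajectory after discarding `burn_in`; for window
#' lengths much longer than the correlation time this is statistically
#' equivalent to independent replicates at a fraction of the cost.
#'
#' @param seed Integer seed (`set.seed` is called before simulating);
#'   `NULL` uses the current RNG state.
#' @param total_time Total simulated time (> `burn_in`).
#' @param burn_in Time discarded before statistics are collected.
#' @param n_replicates Number of analysis windows (>= 1).
#' @param sample_interval Spacing of point samples used for stationary
#'   statistics; `NA` picks a default of a few correlation times.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, total_time, burn_in = 0,
                       n_replicates = 1L, sample_interval = NA) {
  stopifnot(total_time > burn_in, n_replicates >= 1)
  structure(list(seed = seed, total_time = total_time, burn_in = burn_in,
                 n_replicates = as.integer(n_replicates),
                 sample_interval = sample_interval),
            class = "sim_config")
}

.apply_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  invisible(NULL)
}

.new_trace_stats <- function(stationary_mean, stationary_variance,
                             time_avg_variance, se, autocovariance = NULL,
                             arrival_count_variance = NA_real_,
                             extra = list()) {
  structure(c(list(stationary_mean = stationary_mean,
                   stationary_variance = stationary_variance,
                   time_avg_variance = time_avg_variance,
                   autocovariance = autocovariance,
                   arrival_count_variance = arrival_count_variance,
                   se = se), extra),
            class = "trace_stats")
}

#' @export
print.trace_stats <- function(x, ...) {
  cat(sprintf(paste0("trace statistics: mean = %.4g (se %.2g), variance = ",
                     "%.4g, time-averaged variance = %.4g (se %.2g)\n"),
              x$stationary_mean, x$se$stationary_mean, x$stationary_variance,
              x$time_avg_variance, x$se$time_avg_variance))
  invisible(x)
}

#' Exact simulation of a birth-death process
#'
#' Gillespie simulation of constant birth at rate `birth` and
#' per-molecule death at rate `death`. The stationary distribution is
#' Poisson(`birth/death`); the variance of the window-averaged count is
#' \eqn{2 m \tau / T} with \eqn{\tau = 1/\mathrm{death}}, i.e.
#' `time_avg_variance * T / (mean * tau)` converges to 2.
#'
#' @param birth Birth (arrival) rate.
#' @param death Per-molecule death rate.
#' @param config A [sim_config()].
#' @return A `trace_stats` object; component `window_means` holds the
#'   per-window averages, `window_arrivals` the per-window birth counts.
#' @export
simulate_birth_death <- function(birth, death, config) {
  stopifnot(birth > 0, death > 0, inherits(config, "sim_config"))
  window <- (config$total_time - config$burn_in) / config$n_replicates
  if (window < 10 / death)
    warning("window length < 10/death: T >> tau assumption violated")
  si <- config$sample_interval
  if (is.na(si)) si <- 3 / death
  .apply_seed(config)
  res <- ssa_grid_cpp(nx = 1L, ny = 1L, hx = 0, hy = 0, nu = death,
                      prod = birth, cell_map = 0L, n_cells = 1L,
                      burn_in = config$burn_in,
                      n_windows = config$n_replicates, window = window,
                      sample_interval = si, track = 0L)
  x <- as.numeric(res$samples)
  wm <- as.numeric(res$window_means)
  wa <- as.numeric(res$window_arrivals)
  R <- length(wm)
  se <- list(stationary_mean = sd(x) / sqrt(length(x)),
             stationary_variance = sd((x - mean(x))^2) / sqrt(length(x)),
             time_avg_variance = var(wm) * sqrt(2 / max(R - 1, 1)))
  .new_trace_stats(mean(x), var(x), var(wm), se,
                   arrival_count_variance = var(wa),
                   extra = list(window_means = wm, window_arrivals = wa,
                                window = window))
}

#' Transport-delay samplers for the generalised DT model
#'
#' Factories returning samplers `function(n)` of non-negative delays:
#' a deterministic delay, an exponential delay, and the first-passage
#' time of the biased telegraph motion inside a cytoneme of length `L`
#' (forward/backward velocities `v_plus`/`v_minus`, switching rates
#' `zeta_plus`/`zeta_minus`), where a molecule returning to the source
#' re-enters the cytoneme after an exponential residence time with rate
#' `gamma_entry`.
#'
#' @param tau0,mean Delay value / mean delay.
#' @param L,v_plus,v_minus,zeta_plus,zeta_minus,gamma_entry Telegraph
#'   first-passage parameters.
#' @return A function of `n` returning `n` sampled delays.
#' @name delay_samplers
#' @export
delay_deterministic <- function(tau0) {
  stopifnot(tau0 >= 0)
  function(n) rep(tau0, n)
}

#' @rdname delay_samplers
#' @export
delay_exponential <- function(mean) {
  stopifnot(mean > 0)
  function(n) rexp(n, rate = 1 / mean)
}

#' @rdname delay_samplers
#' @export
delay_telegraph <- function(L, v_plus = 1, v_minus = 1, zeta_plus = 1,
                            zeta_minus = 1, gamma_entry = 1) {
  stopifnot(L > 0, v_plus > 0, v_minus > 0, zeta_plus > 0, zeta_minus > 0,
            gamma_entry > 0)
  function(n) {
    vapply(seq_len(n), function(i) {
      t_tot <- 0
      repeat {
        x <- 0; forward <- TRUE
        repeat {
          run <- rexp(1, if (forward) zeta_plus else zeta_minus)
          v <- if (forward) v_plus else -v_minus
          x_new <- x + v * run
          if (forward && x_new >= L) {       # absorbed at the target end
            t_tot <- t_tot + (L - x) / v_plus
            return(t_tot)
          }
          if (!forward && x_new <= 0) {      # back into the source cell
            t_tot <- t_tot + x / v_minus + rexp(1, gamma_entry)
            break
          }
          t_tot <- t_tot + run
          x <- x_new
          forward <- !forward
        }
      }
    }, numeric(1))
  }
}

#' Generalised direct-transport simulation with an arbitrary delay law
#'
#' Molecules are produced as a Poisson process at rate `beta`, reach the
#' target after an independent random delay drawn from `delay_sampler`
#' (any stationary transport law), and then degrade at rate `nu`. Because
#' the molecules are independent, the arrival process at the target is
#' Poisson at rate `beta` whatever the delay distribution, so the
#' stationary count statistics are exactly those of a birth-death
#' process: this simulator verifies that equivalence empirically. With a
#' `routing` probability vector, each molecule is independently assigned
#' to a target cell and per-cell statistics are returned.
#'
#' @param beta Production rate.
#' @param delay_sampler A `function(n)` returning non-negative delays
#'   (see [delay_samplers]).
#' @param nu Degradation rate in the target.
#' @param config A [sim_config()]; `burn_in` must exceed the bulk of the
#'   delay distribution plus several `1/nu`.
#' @param routing Optional probability vector over target cells (sums to
#'   at most 1; the remainder never arrives).
#' @return A `trace_stats` object (single target), or a list with
#'   per-cell `stationary_mean`/`se` and the pooled stats when `routing`
#'   is given. Component `arrival_times` holds the post-burn-in arrival
#'   times of the (pooled) target stream.
#' @export
simulate_generalized_dt <- function(beta, delay_sampler, nu, config,
                                    routing = NULL) {
  stopifnot(beta > 0, nu > 0, is.function(delay_sampler),
            inherits(config, "sim_config"))
  .apply_seed(config)
  n_prod <- rpois(1, beta * config$total_time)
  t_prod <- sort(runif(n_prod, 0, config$total_time))
  delay <- delay_sampler(n_prod)
  if (any(delay < 0)) stop("delay sampler returned negative values")
  arr <- t_prod + delay
  dep <- arr + rexp(n_prod, nu)
  t0 <- config$burn_in; t1 <- config$total_time
  si <- config$sample_interval
  if (is.na(si)) si <- 3 / nu
  t_s <- seq(t0, t1, by = si)
  count_at <- function(a, d) findInterval(t_s, sort(a)) -
    findInterval(t_s, sort(d))
  window <- (t1 - t0) / config$n_replicates
  wbound <- t0 + window * (0:config$n_replicates)
  wmean_of <- function(a, d) {
    vapply(seq_len(config$n_replicates), function(k) {
      lo <- wbound[k]; hi <- wbound[k + 1]
      keep <- a < hi & d > lo
      sum(pmin(d[keep], hi) - pmax(a[keep], lo)) / window
    }, numeric(1))
  }
  if (is.null(routing)) {
    x <- count_at(arr, dep)
    wm <- wmean_of(arr, dep)
    keep_arr <- arr[arr >= t0 & arr <= t1]
    se <- list(stationary_mean = sd(x) / sqrt(length(x)),
               stationary_variance = sd((x - mean(x))^2) / sqrt(length(x)),
               time_avg_variance = var(wm) *
                 sqrt(2 / max(length(wm) - 1, 1)),
               fano = NULL)
    fano <- var(x) / mean(x)
    se$fano <- fano * sqrt(2 / length(x) + 1 / (mean(x) * length(x)))
    .new_trace_stats(mean(x), var(x), var(wm), se,
                     extra = list(window_means = wm, fano = fano,
                                  arrival_times = sort(keep_arr),
                                  window = window))
  } else {
    stopifnot(all(routing >= 0), sum(routing) <= 1 + 1e-12)
    cell <- sample.int(length(routing) + 1L, n_prod, replace = TRUE,
                       prob = c(routing, max(0, 1 - sum(routing))))
    per_cell <- lapply(seq_along(routing), function(cc) {
      k <- cell == cc
      x <- count_at(arr[k], dep[k])
      list(mean = mean(x), se = sd(x) / sqrt(length(x)))
    })
    list(cell_means = vapply(per_cell, `[[`, numeric(1), "mean"),
         cell_se = vapply(per_cell, `[[`, numeric(1), "se"))
  }
}

#' Concentration versus arrival-count readout
#'
#' For the same simulated birth-death trajectory, compares two readouts
#' per window: (i) the time-averaged molecule count and (ii) the raw
#' number of arrival events. Counting arrivals eliminates degradation
#' noise but keeps arrival noise, so in the long-window limit the ratio
#' of squared coefficients of variation (i over ii) converges to 2: at
#' best a factor-of-2 variance reduction.
#'
#' @inheritParams simulate_birth_death
#' @return The CV-squared ratio, with attributes `se` (delete-one
#'   jackknife over windows), `cv2_concentration`, `cv2_arrival`.
#' @export
arrival_vs_concentration_cv <- function(birth, death, config) {
  bd <- simulate_birth_death(birth, death, config)
  x <- bd$window_means; y <- bd$window_arrivals
  cv2 <- function(v) var(v) / mean(v)^2
  ratio <- cv2(x) / cv2(y)
  R <- length(x)
  loo <- vapply(seq_len(R), function(i) cv2(x[-i]) / cv2(y[-i]), numeric(1))
  se <- sqrt((R - 1) / R * sum((loo - mean(loo))^2))
  structure(ratio, se = se, cv2_concentration = cv2(x), cv2_arrival = cv2(y))
}

#' Exact simulation of the SDC model on a subcell lattice
#'
#' Gillespie simulation of the 1D synthesis-diffusion-clearance system:
#' each cell of width `2a` is split into `subcells_per_cell` compartments,
#' molecules hop between adjacent compartments at rate
#' \eqn{D/\Delta x^2}, degrade anywhere at rate `nu`, and are produced at
#' rate `beta` at the origin (split across the two central subcells).
#' Counts are aggregated per cell. Stationary means converge to
#' [mean_profile_sdc()] and window-averaged variances to
#' \eqn{2 m_j \tau_{SDC} / T}: the decisive stochastic check of the
#' correlation-time bracket.
#'
#' @param beta,D,nu,a Physical SDC parameters.
#' @param n_cells Target cells on each side of the source.
#' @param subcells_per_cell Even number of compartments per cell width
#'   (>= 8 for the variance contract).
#' @param config A [sim_config()].
#' @param probe_cells Cell indices `j >= 1` whose statistics are needed;
#'   the reflecting boundary must be at least `5*lambda` beyond the
#'   outermost probed cell, otherwise an error is raised.
#' @return List with data frame `cells` (`j`, `mean`, `mean_se`,
#'   `time_avg_variance`, `tav_se`), `window`, and matrix
#'   `window_means`.
#' @export
simulate_sdc_lattice <- function(beta, D, nu, a, n_cells, subcells_per_cell,
                                 config, probe_cells = NULL) {
  stopifnot(beta > 0, D > 0, nu > 0, a > 0, n_cells >= 2,
            subcells_per_cell %% 2 == 0, inherits(config, "sim_config"))
  lambda <- sqrt(D / nu)
  if (is.null(probe_cells)) probe_cells <- seq_len(min(n_cells, 5))
  stopifnot(all(probe_cells >= 1), all(probe_cells <= n_cells))
  boundary_gap <- (2 * n_cells + 1) * a - (2 * max(probe_cells) + 1) * a
  if (boundary_gap < 5 * lambda)
    stop(sprintf(paste0("reflecting boundary only %.3g lengths from the ",
                        "outermost probed cell (need >= 5): increase ",
                        "n_cells"), boundary_gap / lambda))
  S <- as.integer(subcells_per_cell)
  n_side <- n_cells * S + S %/% 2L         # subcells from 0 to the boundary
  nx <- 2L * n_side
  delta <- 2 * a / S
  h <- D / delta^2
  prod <- numeric(nx); prod[c(n_side, n_side + 1L)] <- beta / 2
  ## the source cell and every target cell are S subcells wide, so cells
  ## tile the lattice: ids 0..n_cells-1 left, n_cells = source, n_cells+j
  ## = right-hand cell j
  cell_map <- rep(0:(2L * n_cells), each = S)
  n_cells_tot <- 2L * n_cells + 1L
  window <- (config$total_time - config$burn_in) / config$n_replicates
  tau <- correlation_time_sdc(lambda / a, nu)
  if (window < 10 * tau)
    warning("window length < 10*tau: T >> tau assumption violated")
  .apply_seed(config)
  res <- ssa_grid_cpp(nx = nx, ny = 1L, hx = h, hy = 0, nu = nu,
                      prod = prod, cell_map = cell_map,
                      n_cells = n_cells_tot, burn_in = config$burn_in,
                      n_windows = config$n_replicates, window = window,
                      sample_interval = -1, track = integer(0))
  wm <- res$window_means                    # n_windows x n_cells_tot
  idx <- n_cells + 1L + probe_cells         # right-side probed cells
  R <- nrow(wm)
  cells <- data.frame(
    j = probe_cells,
    mean = colMeans(wm[, idx, drop = FALSE]),
    mean_se = apply(wm[, idx, drop = FALSE], 2, sd) / sqrt(R),
    time_avg_variance = apply(wm[, idx, drop = FALSE], 2, var),
    tav_se = apply(wm[, idx, drop = FALSE], 2, var) * sqrt(2 / (R - 1)))
  list(cells = cells, window = window, window_means = wm,
       all_cell_means = colMeans(wm), cell_map = cell_map)
}

#' Exact simulation of the discrete-hopping chain
#'
#' Gillespie simulation of a chain of `n_cells` cells with uniform
#' production `mean_count * nu` per cell, hop rate `h` to each
#' neighbour, and degradation `nu`; samples the centre cell at regular
#' intervals. Used to validate [autocorrelation_hopping()]. The chain is
#' long enough (at least `25 * max(1, sqrt(h/nu))` cells on each side of
#' the centre) that boundary effects on the probed cell are negligible.
#'
#' @param h Hop rate; `nu` degradation rate; `mean_count` target
#'   stationary mean per cell.
#' @param config A [sim_config()]; `sample_interval` sets the lag
#'   resolution of the returned series.
#' @param n_cells Optional chain length override (odd).
#' @return List with `series` (centre-cell counts), `dt` (sampling
#'   interval) and `mean_count`.
#' @export
simulate_hopping_chain <- function(h, nu, mean_count, config,
                                   n_cells = NULL) {
  stopifnot(h >= 0, nu > 0, mean_count > 0, inherits(config, "sim_config"))
  if (is.null(n_cells))
    n_cells <- 2L * as.integer(ceiling(25 * max(1, sqrt(h / nu)))) + 1L
  if (n_cells %% 2L == 0L) n_cells <- n_cells + 1L
  si <- config$sample_interval
  if (is.na(si)) si <- 0.25 / (2 * h + nu)
  centre <- (n_cells + 1L) %/% 2L
  .apply_seed(config)
  res <- ssa_grid_cpp(nx = n_cells, ny = 1L, hx = h, hy = 0, nu = nu,
                      prod = rep(mean_count * nu, n_cells),
                      cell_map = seq_len(n_cells) - 1L, n_cells = n_cells,
                      burn_in = config$burn_in, n_windows = 1L,
                      window = config$total_time - config$burn_in,
                      sample_interval = si, track = centre - 1L)
  list(series = as.numeric(res$samples), dt = si, mean_count = mean_count,
       n_cells = n_cells)
}

#' Empirical autocovariance with batch standard errors
#'
#' @param series Regularly sampled counts.
#' @param dt Sampling interval.
#' @param lags Lag times (multiples of `dt`).
#' @param n_batches Number of batches for the standard error.
#' @return Data frame with `lag`, `autocovariance`, `se`.
#' @export
empirical_autocovariance <- function(series, dt, lags, n_batches = 10) {
  ks <- round(lags / dt)
  stopifnot(max(abs(ks * dt - lags)) < 1e-8 * max(dt, lags))
  n <- length(series)
  bsize <- n %/% n_batches
  est <- vapply(ks, function(k) {
    per_batch <- vapply(seq_len(n_batches), function(b) {
      x <- series[((b - 1) * bsize + 1):(b * bsize)]
      nn <- length(x) - k
      mean((x[1:nn] - mean(x)) * (x[(k + 1):(k + nn)] - mean(x)))
    }, numeric(1))
    c(mean(per_batch), sd(per_batch) / sqrt(n_batches))
  }, numeric(2))
  data.frame(lag = ks * dt, autocovariance = est[1, ], se = est[2, ])
}

#' Microscopic cytoneme transport parameters
#'
#' Houses the transport rates of the cytoneme model: molecules enter each
#' cytoneme at rate `gamma_entry`, run forward at `v_plus` / backward at
#' `v_minus`, and switch direction at rates `zeta_plus`
#' (forward-to-backward) and `zeta_minus`. Derived quantities: run
#' lengths \eqn{d_\pm = v_\pm/\zeta_\pm}, shape
#' \eqn{\phi = \log(d_-/d_+)} and \eqn{\kappa = 1/d_+ - 1/d_-}.
#'
#' @param v_plus,v_minus Forward/backward speeds.
#' @param zeta_plus,zeta_minus Direction-switching rates.
#' @param gamma_entry Cytoneme entry rate from the source.
#' @param beta,nu Production and target-degradation rates.
#' @param N Target cells per side; `a` cell radius (cytoneme `j` has
#'   length `2ja`).
#' @return Object of class `cytoneme_params` with derived `phi` and
#'   `kappa_a`.
#' @export
cytoneme_micro_params <- function(v_plus, v_minus, zeta_plus, zeta_minus,
                                  gamma_entry, beta, nu, N, a = 1) {
  stopifnot(v_plus > 0, v_minus > 0, zeta_plus > 0, zeta_minus > 0,
            gamma_entry > 0, beta > 0, nu > 0, N >= 1, a > 0)
  d_plus <- v_plus / zeta_plus
  d_minus <- v_minus / zeta_minus
  structure(list(v_plus = v_plus, v_minus = v_minus, zeta_plus = zeta_plus,
                 zeta_minus = zeta_minus, gamma_entry = gamma_entry,
                 beta = beta, nu = nu, N = as.integer(N), a = a,
                 d_plus = d_plus, d_minus = d_minus,
                 phi = log(d_minus / d_plus),
                 kappa_a = a * (1 / d_plus - 1 / d_minus)),
            class = "cytoneme_params")
}

#' Microscopic parameters realising a given DT shape
#'
#' Chooses switching rates (at unit speeds) so that the derived
#' \eqn{(\phi, \kappa a)} match a [dt_shape()]; the entry rate `gamma`
#' cancels from the steady state and is arbitrary.
#'
#' @param shape A [dt_shape()] object (kappa branch).
#' @param beta,nu Production/degradation rates.
#' @param v_plus,v_minus,gamma_entry Free microscopic scales.
#' @param a Cell radius.
#' @return A [cytoneme_micro_params()] object.
#' @export
cytoneme_params_from_shape <- function(shape, beta, nu, v_plus = 1,
                                       v_minus = 1, gamma_entry = 1, a = 1) {
  stopifnot(inherits(shape, "dt_shape"), !shape$power_law)
  ## kappa = (1 - e^{-phi})/d+  =>  d+ = a * (1 - e^{-phi})/(kappa*a)
  d_plus <- a * (-expm1(-shape$phi)) / shape$kappa_a
  d_minus <- d_plus * exp(shape$phi)
  cytoneme_micro_params(v_plus, v_minus, v_plus / d_plus, v_minus / d_minus,
                        gamma_entry, beta, nu, shape$N, a)
}

#' Deterministic steady state of the cytoneme transport equations
#'
#' Integrates the mean-field transport system (densities of forward- and
#' backward-moving molecules along each cytoneme, coupled to the source
#' and target counts) to steady state with first-order upwind advection
#' and a CFL-limited explicit step. The steady-state target counts
#' converge to the closed-form DT profile as the grid is refined, and
#' total degradation flux balances production.
#'
#' @param params A [cytoneme_micro_params()] object.
#' @param grid_points Spatial points per cytoneme (>= 50; >= 400 for the
#'   0.5% contract).
#' @param tol Convergence tolerance: maximum relative change of any
#'   target count per unit time.
#' @param t_max Hard cap on integrated time.
#' @return List with `m` (target counts `1..N`), `m0`, `t_final`,
#'   `converged`, `flux_error` (relative production/degradation
#'   imbalance).
#' @export
integrate_cytoneme_ode <- function(params, grid_points = 400, tol = 1e-10,
                                   t_max = 2000) {
  stopifnot(inherits(params, "cytoneme_params"), grid_points >= 50)
  res <- cytoneme_steady_cpp(
    N = params$N, a = params$a, v_plus = params$v_plus,
    v_minus = params$v_minus, zeta_plus = params$zeta_plus,
    zeta_minus = params$zeta_minus, gamma_entry = params$gamma_entry,
    beta = params$beta, nu = params$nu, n_grid = as.integer(grid_points),
    tol = tol, t_max = t_max, cfl = 0.4)
  if (!res$converged)
    warning("cytoneme integrator did not reach steady state by t_max")
  res
}
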