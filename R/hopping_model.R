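## Discrete-hopping simplification of the SDC model: molecules hop between
## adjacent cells at rate h and degrade at rate nu; on an effectively
## infinite chain the count autocovariance of one cell is Bessel-shaped.

#' Parameters of the discrete-hopping model
#'
#' @param h Hop rate to each adjacent cell (>= 0).
#' @param nu Degradation rate (> 0).
#' @param m_j Stationary mean count in the probed cell (> 0).
#' @return Object of class `hopping_params`.
#' @export
hopping_params <- function(h, nu, m_j) {
  stopifnot(h >= 0, nu > 0, m_j > 0)
  structure(list(h = h, nu = nu, m_j = m_j), class = "hopping_params")
}

#' Autocovariance of one cell's count in the hopping model
#'
#' \eqn{C_j(t) = m_j I_0(2ht) e^{-(2h+\nu)t}} with \eqn{I_0} the zeroth
#' modified Bessel function of the first kind; \eqn{C_j(0) = m_j}
#' (Poisson variance equals the mean) and \eqn{h = 0} recovers the pure
#' birth-death autocovariance \eqn{m_j e^{-\nu t}}. Evaluated with the
#' exponentially scaled Bessel function so large \eqn{2ht} cannot
#' overflow.
#'
#' @param params A [hopping_params()] object.
#' @param t Non-negative lag (vectorised).
#' @return Autocovariance at lag `t`.
#' @export
autocorrelation_hopping <- function(params, t) {
  stopifnot(inherits(params, "hopping_params"), all(t >= 0))
  ## I0(2ht) e^{-(2h+nu)t} = [I0(2ht) e^{-2ht}] e^{-nu t}
  params$m_j * besselI(2 * params$h * t, 0, expon.scaled = TRUE) *
    exp(-params$nu * t)
}

#' Correlation time of the hopping model
#'
#' \eqn{\tau = \int_0^\infty C_j(t)\,dt / C_j(0) = [\nu(4h+\nu)]^{-1/2}},
#' decreasing in both the hop and degradation rates. In the fast-hopping
#' limit \eqn{h \gg \nu} it becomes \eqn{(4\nu h)^{-1/2}}, which matches
#' the fast-diffusion limit of [correlation_time_sdc()] with
#' \eqn{h = D/(2a)^2}.
#'
#' @param h Hop rate (>= 0, vectorised).
#' @param nu Degradation rate (> 0).
#' @return Correlation time.
#' @export
correlation_time_hopping <- function(h, nu) {
  stopifnot(all(h >= 0), all(nu > 0))
  1 / sqrt(nu * (4 * h + nu))
}
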