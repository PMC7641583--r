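## Independent oracles used by the tests. These deliberately avoid the
## package's internal code paths: Gamma is evaluated from its literal
## definition, lengthscales by quadrature, and the DT/SDC comparison by a
## dense grid scan, so agreement with the package is a genuine
## cross-check rather than a tautology.

## literal Gamma_j (no expm1 tricks)
gamma_literal <- function(phi, kappa_a, j) {
  exp(-2 * j * kappa_a) * (1 - exp(-phi)) / (1 - exp(-phi - 2 * j * kappa_a))
}

## lengthscale by direct quadrature of Gamma(j) over j (in units of a,
## cells at x = 2ja); substituting t = 2*kappa_a*j makes the integrand
## kappa-free and the integral numerically benign
lengthscale_quadrature <- function(phi, kappa_a) {
  I <- integrate(function(t) exp(-t) * (1 - exp(-phi)) /
                   (1 - exp(-phi - t)),
                 0, Inf, rel.tol = 1e-10)$value
  I / kappa_a
}

## invert the quadrature lengthscale for kappa_a (phi > 0)
solve_kappa_quadrature <- function(phi, lambda_hat) {
  I <- integrate(function(t) exp(-t) * (1 - exp(-phi)) /
                   (1 - exp(-phi - t)),
                 0, Inf, rel.tol = 1e-10)$value
  I / lambda_hat
}

## brute-force DT precision over a dense phi grid: returns max_phi P^2_j
## for every j (beta = T = nu = 1), entirely independent arithmetic
dt_p2_best_bruteforce <- function(N, lambda_hat, j_set,
                                  phi_grid = exp(seq(log(1e-3), log(30),
                                                     length.out = 1500)),
                                  invert = c("closed", "quadrature")) {
  invert <- match.arg(invert)
  best <- rep(-Inf, length(j_set))
  jj <- seq_len(N)
  for (phi in phi_grid) {
    ka <- if (invert == "closed")
      (exp(phi) - 1) * (phi - log(exp(phi) - 1)) / lambda_hat
    else solve_kappa_quadrature(phi, lambda_hat)
    g <- gamma_literal(phi, ka, jj)
    m <- g / (2 * sum(g))
    p2 <- (m[j_set] - m[j_set + 1])^2 / (2 * m[j_set])
    best <- pmax(best, p2)
  }
  best
}

## literal SDC bracket, exactly as printed (naive grouping arithmetic)
sdc_bracket_literal <- function(lh) {
  1 - ((2 / lh) + sinh(2 / lh)) / (4 * sinh(1 / lh) * exp(1 / lh))
}

## brute-force fraction of cells favouring SDC and its 50% crossover
fraction_sdc_bruteforce <- function(N, lambda_hat, n_phi = 1500) {
  p2dt <- dt_p2_best_bruteforce(N, lambda_hat, seq_len(N - 1),
                                phi_grid = exp(seq(log(1e-3), log(30),
                                                   length.out = n_phi)))
  m <- sinh(1 / lambda_hat) * exp(-2 * seq_len(N) / lambda_hat)
  tau <- sdc_bracket_literal(lambda_hat)
  p2sdc <- (m[seq_len(N - 1)] / (2 * tau)) * (1 - exp(-2 / lambda_hat))^2
  mean(p2dt / p2sdc <= 1)
}

lambda50_bruteforce <- function(N, n_phi = 1500) {
  f <- function(lh) fraction_sdc_bruteforce(N, lh, n_phi)
  lo <- 1; hi <- 100
  while (f(lo) >= 0.5) lo <- lo / 2
  while (f(hi) < 0.5) hi <- hi * 2
  while ((hi - lo) / hi > 1e-3) {
    mid <- sqrt(lo * hi)
    if (f(mid) >= 0.5) hi <- mid else lo <- mid
  }
  hi
}

## standard-error helper for a difference of independent estimates
z_diff <- function(a, se_a, b, se_b = 0) (a - b) / sqrt(se_a^2 + se_b^2)
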