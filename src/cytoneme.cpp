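#include <Rcpp.h>
using namespace Rcpp;

// Deterministic integration of the mean-field cytoneme transport system
// to steady state. Cytoneme j (length L_j = 2ja) carries densities of
// forward movers u+ (speed v+, switching to backward at zeta+) and
// backward movers u- (speed v-, switching at zeta-) on nodes
// x_i = i * dx, i = 0..n. Boundary conditions are Dirichlet on the
// inflow characteristics: v+ u+(0) = gamma * m0 (entry from the source)
// and u-(L) = 0; the forward flux v+ u+(L) feeds target j and the
// backward flux v- u-(0) returns to the source. Targets exist on both
// sides of the source (symmetry factor 2 in the source balance).
//
// Spatial derivatives are second-order one-sided upwind, first order at
// the node adjacent to each inflow boundary; time stepping is Heun's
// method (RK2) with a CFL-limited step, which is stable for this
// near-imaginary advection spectrum where forward Euler is not.
// Convergence requires both a relative change below tol per unit time
// and production/degradation flux balance (the latter guards against
// declaring steady state while molecules are still in transit).

struct CytState {
  std::vector<std::vector<double>> up, um;
  std::vector<double> m;
  double m0;
};

// [[Rcpp::export]]
List cytoneme_steady_cpp(int N, double a, double v_plus, double v_minus,
                         double zeta_plus, double zeta_minus,
                         double gamma_entry, double beta, double nu,
                         int n_grid, double tol, double t_max, double cfl) {
  const int n = n_grid;            // nodes 0..n
  std::vector<double> dx(N);
  for (int j = 0; j < N; ++j) dx[j] = 2.0 * a * (double)(j + 1) / (double)n;
  double vmax = std::max(v_plus, v_minus);
  double dt = cfl * dx[0] / vmax;
  double rmax = std::max(zeta_plus, zeta_minus) + nu +
    2.0 * (double)N * gamma_entry;
  if (dt * rmax > cfl) dt = cfl / rmax;

  CytState s;
  s.up.assign(N, std::vector<double>(n + 1, 0.0));
  s.um.assign(N, std::vector<double>(n + 1, 0.0));
  s.m.assign(N, 0.0);
  s.m0 = beta / (2.0 * (double)N * gamma_entry);  // rough start
  CytState d1 = s, d2 = s, tmp = s;

  auto deriv = [&](const CytState &x, CytState &d) {
    double return_flux = 0.0, entry = gamma_entry * x.m0;
    for (int j = 0; j < N; ++j) {
      double idx = 1.0 / dx[j];
      const std::vector<double> &u = x.up[j], &w = x.um[j];
      std::vector<double> &du = d.up[j], &dw = d.um[j];
      // inflow nodes relax fast onto their Dirichlet values
      du[0] = (entry / v_plus - u[0]) / dt;
      for (int i = 1; i <= n; ++i) {
        double dxu = (i == 1)
          ? (u[1] - u[0]) * idx
          : (3.0 * u[i] - 4.0 * u[i - 1] + u[i - 2]) * (0.5 * idx);
        du[i] = -v_plus * dxu + zeta_minus * w[i] - zeta_plus * u[i];
      }
      dw[n] = (0.0 - w[n]) / dt;
      for (int i = 0; i < n; ++i) {
        double dxw = (i == n - 1)
          ? (w[n] - w[n - 1]) * idx
          : (-3.0 * w[i] + 4.0 * w[i + 1] - w[i + 2]) * (0.5 * idx);
        dw[i] = v_minus * dxw + zeta_plus * u[i] - zeta_minus * w[i];
      }
      return_flux += v_minus * w[0];
      d.m[j] = v_plus * u[n] - nu * x.m[j];
    }
    d.m0 = beta - 2.0 * ((double)N * entry - return_flux);
  };
  auto axpy = [&](const CytState &x, const CytState &d, double h,
                  CytState &out) {
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i <= n; ++i) {
        out.up[j][i] = x.up[j][i] + h * d.up[j][i];
        out.um[j][i] = x.um[j][i] + h * d.um[j][i];
      }
      out.m[j] = x.m[j] + h * d.m[j];
    }
    out.m0 = x.m0 + h * d.m0;
  };

  std::vector<double> m_prev(N, 0.0);
  double t = 0.0, t_check = 1.0;
  bool converged = false;

  while (t < t_max) {
    deriv(s, d1);
    axpy(s, d1, dt, tmp);
    deriv(tmp, d2);
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i <= n; ++i) {
        s.up[j][i] += 0.5 * dt * (d1.up[j][i] + d2.up[j][i]);
        s.um[j][i] += 0.5 * dt * (d1.um[j][i] + d2.um[j][i]);
      }
      s.m[j] += 0.5 * dt * (d1.m[j] + d2.m[j]);
    }
    s.m0 += 0.5 * dt * (d1.m0 + d2.m0);
    // pin the inflow nodes exactly
    double entry = gamma_entry * s.m0;
    for (int j = 0; j < N; ++j) {
      s.up[j][0] = entry / v_plus;
      s.um[j][n] = 0.0;
    }
    t += dt;
    if (t >= t_check) {
      double rel = 0.0, deg = 0.0;
      for (int j = 0; j < N; ++j) {
        double denom = std::max(s.m[j], 1e-300);
        rel = std::max(rel, std::fabs(s.m[j] - m_prev[j]) / denom);
        m_prev[j] = s.m[j];
        deg += 2.0 * nu * s.m[j];
      }
      if (rel < tol && std::fabs(deg - beta) / beta < 1e-3) {
        converged = true; break;
      }
      t_check = t + 1.0;
    }
  }
  double total_deg = 0.0;
  for (int j = 0; j < N; ++j) total_deg += 2.0 * nu * s.m[j];
  return List::create(_["m"] = NumericVector(s.m.begin(), s.m.end()),
                      _["m0"] = s.m0, _["t_final"] = t,
                      _["converged"] = converged,
                      _["flux_error"] = std::fabs(total_deg - beta) / beta);
}
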