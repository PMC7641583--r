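#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven (Gillespie) simulation of a first-order
// reaction-diffusion lattice: production into fixed compartments,
// nearest-neighbour hopping (rate hx along x, hy along y; reflecting in
// x, periodic in y), and uniform per-molecule degradation nu.
//
// Every molecule has the same total event rate (boundary hops are kept
// as null self-loops, a uniformisation that preserves the law of the
// process), so event selection is O(1) with a molecule list.
//
// Statistics are collected per *cell* (groups of compartments given by
// cell_map): exact time integrals of the count over consecutive
// windows, production-event counts per window, and point samples of
// tracked cells at regular intervals. Uses R's RNG (unif_rand), so
// set.seed() governs reproducibility.
//
// [[Rcpp::export]]
List ssa_grid_cpp(int nx, int ny, double hx, double hy, double nu,
                  NumericVector prod, IntegerVector cell_map, int n_cells,
                  double burn_in, int n_windows, double window,
                  double sample_interval, IntegerVector track) {
  const int ncomp = nx * ny;
  if (prod.size() != ncomp || cell_map.size() != ncomp)
    stop("prod and cell_map must have length nx*ny");
  double P = 0.0;
  std::vector<double> cum_prod(ncomp);
  for (int i = 0; i < ncomp; ++i) { P += prod[i]; cum_prod[i] = P; }
  if (P <= 0) stop("total production must be positive");

  const double rmol = 2.0 * hx + 2.0 * hy + nu;
  const double t_end = burn_in + n_windows * window;

  std::vector<int> pos;              // compartment of each molecule
  pos.reserve(4096);
  std::vector<int> cell_count(n_cells, 0);
  std::vector<double> cell_last(n_cells, 0.0), cell_integral(n_cells, 0.0);

  NumericMatrix window_means(n_windows, n_cells);
  NumericMatrix window_arrivals(n_windows, n_cells);

  const bool do_sample = sample_interval > 0 && track.size() > 0;
  std::vector<double> sample_times;
  int n_samples = 0;
  if (do_sample)
    n_samples = (int)std::floor((t_end - burn_in) / sample_interval) + 1;
  NumericMatrix samples(do_sample ? n_samples : 0,
                        do_sample ? (int)track.size() : 0);
  int sample_idx = 0;
  double next_sample = do_sample ? burn_in : R_PosInf;

  int win = -1;                      // -1 = still in burn-in
  double next_boundary = burn_in;

  double t = 0.0;
  auto touch = [&](int cell, double now) {
    cell_integral[cell] += (double)cell_count[cell] * (now - cell_last[cell]);
    cell_last[cell] = now;
  };

  while (true) {
    double total = P + (double)pos.size() * rmol;
    double dt = -std::log(unif_rand()) / total;
    double t_new = t + dt;

    // emit samples and close windows that fall before the next event
    while (std::min(next_sample, next_boundary) <= t_new) {
      if (next_sample <= next_boundary) {
        if (sample_idx < n_samples) {
          for (int k = 0; k < track.size(); ++k)
            samples(sample_idx, k) = cell_count[track[k]];
          ++sample_idx;
        }
        next_sample += sample_interval;
      } else {
        for (int c = 0; c < n_cells; ++c) {
          touch(c, next_boundary);
          if (win >= 0) window_means(win, c) = cell_integral[c] / window;
          cell_integral[c] = 0.0;
        }
        ++win;
        if (win >= n_windows) {
          return List::create(_["window_means"] = window_means,
                              _["window_arrivals"] = window_arrivals,
                              _["samples"] = samples,
                              _["t_end"] = next_boundary);
        }
        next_boundary = burn_in + (double)(win + 1) * window;
      }
    }

    t = t_new;
    double u = unif_rand() * total;
    if (u < P) {                     // production
      int lo = 0, hi = ncomp - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum_prod[mid] >= u) hi = mid; else lo = mid + 1;
      }
      pos.push_back(lo);
      int c = cell_map[lo];
      touch(c, t);
      cell_count[c] += 1;
      if (win >= 0) window_arrivals(win, c) += 1.0;
    } else {
      double v = u - P;
      int k = (int)(v / rmol);
      if (k >= (int)pos.size()) k = (int)pos.size() - 1;
      double f = v - (double)k * rmol;
      int p = pos[k];
      int x = p % nx, y = p / nx;
      int p_new = p;
      bool dead = false;
      if (f < hx) { if (x > 0) p_new = p - 1; }
      else if (f < 2 * hx) { if (x < nx - 1) p_new = p + 1; }
      else if (f < 2 * hx + hy) { p_new = x + nx * ((y + 1) % ny); }
      else if (f < 2 * hx + 2 * hy) { p_new = x + nx * ((y - 1 + ny) % ny); }
      else dead = true;
      if (dead) {
        int c = cell_map[p];
        touch(c, t);
        cell_count[c] -= 1;
        pos[k] = pos.back();
        pos.pop_back();
      } else if (p_new != p) {
        int c_old = cell_map[p], c_new = cell_map[p_new];
        if (c_old != c_new) {
          touch(c_old, t); touch(c_new, t);
          cell_count[c_old] -= 1;
          cell_count[c_new] += 1;
        }
        pos[k] = p_new;
      }
    }
  }
}
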