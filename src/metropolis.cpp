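#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation on a uniform grid; xi must lie in [x0, x0 + (n-1)*dx].
static inline double interp_energy(const double *e, int n, double x0, double dx,
                                   double xi) {
  double t = (xi - x0) / dx;
  int j = (int)t;
  if (j < 0) j = 0;
  if (j > n - 2) j = n - 2;
  double f = t - j;
  return e[j] * (1.0 - f) + e[j + 1] * f;
}

// Metropolis Monte Carlo on U(xi) = A(xi) + k/2 (xi - c)^2 over a bounded
// domain. A is supplied tabulated on a uniform grid; proposals outside the
// domain are rejected (equivalent to an infinite wall). The step size is
// tuned during burn-in toward a 30-50% acceptance rate. Uses R's RNG so
// set.seed() governs reproducibility.
// [[Rcpp::export(name = ".metropolis_sample")]]
NumericVector metropolis_sample(NumericVector grid_energy, double x0, double dx,
                                double lo, double hi, double bias_center,
                                double bias_k, int n_samples, int burn_in,
                                double beta, double xi_start, double step0,
                                int thin) {
  int ng = grid_energy.size();
  const double *e = REAL(grid_energy);
  NumericVector out(n_samples);
  RNGScope scope;

  double xi = xi_start;
  if (xi < lo) xi = lo;
  if (xi > hi) xi = hi;
  double u_cur = interp_energy(e, ng, x0, dx, xi) +
                 0.5 * bias_k * (xi - bias_center) * (xi - bias_center);
  double step = step0;
  int acc_window = 0, tried_window = 0;
  if (thin < 1) thin = 1;
  long total = (long)burn_in + (long)n_samples * thin;

  for (long i = 0; i < total; ++i) {
    double prop = xi + (unif_rand() * 2.0 - 1.0) * step;
    ++tried_window;
    if (prop >= lo && prop <= hi) {
      double u_new = interp_energy(e, ng, x0, dx, prop) +
                     0.5 * bias_k * (prop - bias_center) * (prop - bias_center);
      double dU = u_new - u_cur;
      if (dU <= 0.0 || unif_rand() < std::exp(-beta * dU)) {
        xi = prop;
        u_cur = u_new;
        ++acc_window;
      }
    }
    // adapt only during burn-in, every 100 proposals
    if (i < burn_in && tried_window == 100) {
      double rate = acc_window / 100.0;
      if (rate < 0.30) step *= 0.8;
      else if (rate > 0.50) step *= 1.25;
      double span = hi - lo;
      if (step > span) step = span;
      if (step < 1e-6) step = 1e-6;
      acc_window = 0;
      tried_window = 0;
    }
    if (i >= burn_in && (i - burn_in) % thin == thin - 1)
      out[(i - burn_in) / thin] = xi;
  }
  return out;
}
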