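#include <Rcpp.h>
using namespace Rcpp;

// Drift lookup by linear interpolation on the uniform field grid; beyond the
// grid the drift is held at its clipped edge value (Levy jumps can exit any
// finite grid).
static inline double drift_at(double x, const double *b, double x0, double h,
                              int n) {
  double u = (x - x0) / h;
  if (u <= 0.0) return b[0];
  int i = (int)u;
  if (i >= n - 1) return b[n - 1];
  double w = u - i;
  return b[i] * (1.0 - w) + b[i + 1] * w;
}

// Standard symmetric alpha-stable variate (characteristic function
// exp(-|w|^alpha)) by the Chambers-Mallows-Stuck transform. Uses R's RNG.
static inline double rsas_std(double alpha) {
  double u = R::runif(-M_PI_2, M_PI_2);
  if (alpha == 1.0) return tan(u);
  double w = R::exp_rand();
  return sin(alpha * u) / pow(cos(u), 1.0 / alpha) *
         pow(cos((1.0 - alpha) * u) / w, (1.0 - alpha) / alpha);
}

// Euler-Maruyama integration of the Levy-driven sampler SDE
//   dx = gamma b(x) dt + beta v dt + gamma^(1/alpha) dL_t^alpha
//   dv = beta b(x) dt
// with the per-step noise increment drawn as SaS(alpha, dt) scaled by
// gamma^(1/alpha). Positions (and running means of the position) are
// recorded every `record_every` steps.
// [[Rcpp::export]]
List fns_simulate_cpp(NumericVector grid, NumericVector bvals, double alpha,
                      double beta, double gamma_noise, double dt, int n_steps,
                      NumericVector x0, NumericVector v0, int record_every) {
  const int nc = x0.size();
  const int n = grid.size();
  const double g0 = grid[0];
  const double h = grid[1] - grid[0];
  const double *b = REAL(bvals);
  const double noise_scale = pow(gamma_noise, 1.0 / alpha) *
                             pow(dt, 1.0 / alpha);
  const int n_rec = n_steps / record_every;
  NumericMatrix pos(n_rec, nc);
  NumericMatrix runmean(n_rec, nc);
  NumericMatrix vel(beta != 0.0 ? n_rec : 0, beta != 0.0 ? nc : 0);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> csum(nc, 0.0);
  int r = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int c = 0; c < nc; ++c) {
      double bx = drift_at(x[c], b, g0, h, n);
      double xn = x[c] + gamma_noise * bx * dt + beta * v[c] * dt +
                  noise_scale * rsas_std(alpha);
      v[c] += beta * bx * dt;
      x[c] = xn;
      csum[c] += xn;
    }
    if (s % record_every == 0) {
      for (int c = 0; c < nc; ++c) {
        pos(r, c) = x[c];
        runmean(r, c) = csum[c] / s;
        if (beta != 0.0) vel(r, c) = v[c];
      }
      ++r;
    }
  }
  return List::create(_["positions"] = pos, _["running_mean"] = runmean,
                      _["momenta"] = vel);
}
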