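#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis Monte Carlo on an analytic Gaussian-well surface plus a
// harmonic restraint U_bias = sum_d k_d (xi_d - c_d)^2 (no 1/2 factor,
// AMBER restraint convention). Uses R's RNG so results are reproducible
// under set.seed(). Step size is tuned to the 30-60% acceptance band
// during burn-in, then frozen.
//
// well_centers: d x nwells, widths: d x nwells, depths: nwells.
// U = conf_k * |x - conf_center|^2 - sum_w depth_w exp(-sum_d (x_d-c_dw)^2 / (2 w_dw^2))

static inline double pot(const NumericMatrix &wc, const NumericVector &depth,
                         const NumericMatrix &wd, const NumericVector &cc,
                         double conf_k, const std::vector<double> &x) {
  const int d = wc.nrow(), nw = wc.ncol();
  double u = 0.0;
  for (int j = 0; j < d; ++j) {
    const double dx = x[j] - cc[j];
    u += conf_k * dx * dx;
  }
  for (int w = 0; w < nw; ++w) {
    double q = 0.0;
    for (int j = 0; j < d; ++j) {
      const double dx = x[j] - wc(j, w);
      q += dx * dx / (2.0 * wd(j, w) * wd(j, w));
    }
    u -= depth[w] * std::exp(-q);
  }
  return u;
}

// [[Rcpp::export]]
List cpp_sample_surface(NumericMatrix well_centers, NumericVector depths,
                        NumericMatrix widths, NumericVector conf_center,
                        double conf_k, NumericVector bias_center,
                        NumericVector bias_k, int n_samples, int burn_in,
                        double step0, double kT, NumericVector start) {
  const int d = well_centers.nrow();
  RNGScope scope;
  std::vector<double> x(start.begin(), start.end());
  std::vector<double> xp(d);
  auto total = [&](const std::vector<double> &p) {
    double u = pot(well_centers, depths, widths, conf_center, conf_k, p);
    for (int j = 0; j < d; ++j) {
      const double dx = p[j] - bias_center[j];
      u += bias_k[j] * dx * dx;
    }
    return u;
  };
  double u = total(x);
  if (!std::isfinite(u)) stop("non-finite potential at start point");
  double step = step0;
  NumericMatrix out(n_samples, d);
  int acc_post = 0, acc_win = 0, win = 0;
  const int total_steps = burn_in + n_samples;
  for (int t = 0; t < total_steps; ++t) {
    for (int j = 0; j < d; ++j) xp[j] = x[j] + (unif_rand() * 2.0 - 1.0) * step;
    const double up = total(xp);
    bool accept = false;
    if (up <= u) {
      accept = true;
    } else {
      accept = unif_rand() < std::exp(-(up - u) / kT);
    }
    if (accept) {
      x = xp;
      u = up;
    }
    if (t < burn_in) {
      acc_win += accept;
      if (++win == 50) {
        const double rate = acc_win / 50.0;
        if (rate > 0.60) step *= 1.2;
        else if (rate < 0.30) step *= 0.8;
        acc_win = 0;
        win = 0;
      }
    } else {
      acc_post += accept;
      for (int j = 0; j < d; ++j) out(t - burn_in, j) = x[j];
    }
  }
  return List::create(_["samples"] = out,
                      _["acceptance"] = (double)acc_post / n_samples,
                      _["step_size"] = step);
}
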