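// Fixed-step RK4 core for the G-function eco-evolutionary model.
// gamma is piecewise constant per integer pseudo-step; within each step the
// coupled population/strategy system is advanced with n_sub classical
// Runge-Kutta substeps.  Guards match the R-level definitions: populations
// floored at zero inside stage evaluations, per-capita decline floored at
// -100 per pseudo-step, strategy velocity capped at 10*sigma_k, and an
// absorbing extinction floor applied after every substep.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Deriv {
  std::vector<double> dx, du;
};

static void deriv(const std::vector<double>& x, const std::vector<double>& u,
                  double gamma, double r, double Km, double sk2, double d,
                  const std::vector<double>& s, double cap, Deriv& out) {
  const int n = x.size();
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += x[i] > 0 ? x[i] : 0.0;
  const double kfloor = Km * std::exp(-60.0);
  for (int i = 0; i < n; ++i) {
    double mis = u[i] - gamma;
    double k = Km * std::exp(-mis * mis / (2.0 * sk2));
    if (k < kfloor) k = kfloor;
    double g = r * (1.0 - tot / k) - d * s[i];
    if (g < -100.0) g = -100.0;
    out.dx[i] = (x[i] > 0 ? x[i] : 0.0) * g;
    double du = s[i] * (-r * tot * mis / (sk2 * k));
    if (du > cap) du = cap;
    if (du < -cap) du = -cap;
    out.du[i] = du;
  }
}

// [[Rcpp::export(name = ".ecoevo_rk4")]]
List ecoevo_rk4(NumericVector x0, NumericVector u0, NumericVector s,
                NumericVector gamma, double r, double Km, double sigma_k,
                double d, int n_sub, double extinction_floor) {
  const int nsp = x0.size(), nt = gamma.size();
  const double sk2 = sigma_k * sigma_k, cap = 10.0 * sigma_k;
  const double h = 1.0 / n_sub;
  std::vector<double> x(x0.begin(), x0.end()), u(u0.begin(), u0.end());
  std::vector<double> sv(s.begin(), s.end());
  std::vector<double> xt(nsp), ut(nsp);
  Deriv k1, k2, k3, k4;
  k1.dx.resize(nsp); k1.du.resize(nsp); k2 = k1; k3 = k1; k4 = k1;
  NumericMatrix xs(nt, nsp), us(nt, nsp);
  for (int t = 0; t < nt; ++t) {
    const double g = gamma[t];
    for (int j = 0; j < n_sub; ++j) {
      deriv(x, u, g, r, Km, sk2, d, sv, cap, k1);
      for (int i = 0; i < nsp; ++i) {
        xt[i] = x[i] + 0.5 * h * k1.dx[i];
        ut[i] = u[i] + 0.5 * h * k1.du[i];
      }
      deriv(xt, ut, g, r, Km, sk2, d, sv, cap, k2);
      for (int i = 0; i < nsp; ++i) {
        xt[i] = x[i] + 0.5 * h * k2.dx[i];
        ut[i] = u[i] + 0.5 * h * k2.du[i];
      }
      deriv(xt, ut, g, r, Km, sk2, d, sv, cap, k3);
      for (int i = 0; i < nsp; ++i) {
        xt[i] = x[i] + h * k3.dx[i];
        ut[i] = u[i] + h * k3.du[i];
      }
      deriv(xt, ut, g, r, Km, sk2, d, sv, cap, k4);
      for (int i = 0; i < nsp; ++i) {
        x[i] += h / 6.0 * (k1.dx[i] + 2.0 * k2.dx[i] + 2.0 * k3.dx[i] + k4.dx[i]);
        u[i] += h / 6.0 * (k1.du[i] + 2.0 * k2.du[i] + 2.0 * k3.du[i] + k4.du[i]);
        if (x[i] < extinction_floor) x[i] = 0.0;
        if (!std::isfinite(x[i]) || !std::isfinite(u[i]))
          stop("non-finite state at pseudo-step %d", t + 1);
      }
    }
    for (int i = 0; i < nsp; ++i) {
      xs(t, i) = x[i];
      us(t, i) = u[i];
    }
  }
  return List::create(_["x"] = xs, _["u"] = us);
}
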