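#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Piecewise-linear insulin forcing through (ft, fy); constant beyond the
// ends, clipped at zero. ft must be strictly increasing.
static inline double interp_forcing(double t, const std::vector<double>& ft,
                                    const std::vector<double>& fy) {
  const int n = (int)ft.size();
  double v;
  if (t <= ft[0]) {
    v = fy[0];
  } else if (t >= ft[n - 1]) {
    v = fy[n - 1];
  } else {
    int hi = (int)(std::upper_bound(ft.begin(), ft.end(), t) - ft.begin());
    int lo = hi - 1;
    double w = (t - ft[lo]) / (ft[hi] - ft[lo]);
    v = fy[lo] + w * (fy[hi] - fy[lo]);
  }
  return v < 0.0 ? 0.0 : v;
}

struct MinmodParms {
  double Sg, p2, p3, Gb, Ib;
};

static inline void rhs(double t, double G, double X, const MinmodParms& p,
                       const std::vector<double>& ft,
                       const std::vector<double>& fy,
                       double& dG, double& dX) {
  double I = interp_forcing(t, ft, fy);
  dG = -(p.Sg + X) * G + p.Sg * p.Gb;
  dX = -p.p2 * X + p.p3 * (I - p.Ib);
}

// Glucose minimal model integrated by classical RK4 with steps aligned to
// the forcing knots and the requested output times, so the right-hand side
// is smooth inside every step. Step size never exceeds hmax (minutes).
//
// State: G (mg/dL), X (min^-1, remote insulin action), with
//   dG/dt = -(Sg + X) G + Sg Gb,   dX/dt = -p2 X + p3 (I(t) - Ib),
//   G(0) = G0, X(0) = 0.
// [[Rcpp::export]]
NumericVector minmod_integrate_cpp(NumericVector t_out, double Sg, double p2,
                                   double p3, double G0, double Gb, double Ib,
                                   NumericVector ftime, NumericVector fval,
                                   double hmax = 0.1) {
  const int nout = t_out.size();
  NumericVector out(nout);
  std::vector<double> ft(ftime.begin(), ftime.end());
  std::vector<double> fy(fval.begin(), fval.end());
  MinmodParms p = {Sg, p2, p3, Gb, Ib};

  // breakpoints: 0, all forcing knots and output times in (0, tmax]
  double tmax = t_out[nout - 1];
  std::vector<double> brk;
  brk.push_back(0.0);
  for (double t : ft) if (t > 0.0 && t <= tmax) brk.push_back(t);
  for (int i = 0; i < nout; ++i) if (t_out[i] > 0.0) brk.push_back(t_out[i]);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end(),
                        [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
            brk.end());

  double G = G0, X = 0.0;
  int iout = 0;
  // output times at (or numerically equal to) zero
  while (iout < nout && t_out[iout] <= 1e-12) out[iout++] = G;

  for (size_t b = 0; b + 1 < brk.size(); ++b) {
    double t0 = brk[b], t1 = brk[b + 1];
    int nstep = (int)std::ceil((t1 - t0) / hmax);
    if (nstep < 1) nstep = 1;
    double h = (t1 - t0) / nstep;
    for (int s = 0; s < nstep; ++s) {
      double t = t0 + s * h;
      double k1G, k1X, k2G, k2X, k3G, k3X, k4G, k4X;
      rhs(t, G, X, p, ft, fy, k1G, k1X);
      rhs(t + h / 2, G + h / 2 * k1G, X + h / 2 * k1X, p, ft, fy, k2G, k2X);
      rhs(t + h / 2, G + h / 2 * k2G, X + h / 2 * k2X, p, ft, fy, k3G, k3X);
      rhs(t + h, G + h * k3G, X + h * k3X, p, ft, fy, k4G, k4X);
      G += h / 6 * (k1G + 2 * k2G + 2 * k3G + k4G);
      X += h / 6 * (k1X + 2 * k2X + 2 * k3X + k4X);
    }
    while (iout < nout && std::fabs(t_out[iout] - t1) < 1e-12) out[iout++] = G;
  }
  if (iout != nout) stop("internal error: output grid not fully covered");
  return out;
}

// Exact two-sided permutation p-value for the Spearman rank correlation:
// enumerates all n! pairings of the (already ranked) vectors and counts
// |rho*| >= |rho_obs|. Feasible for n <= 9.
// [[Rcpp::export]]
double spearman_perm_pvalue_cpp(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (n != ry.size()) stop("length mismatch");
  if (n > 9) stop("exact permutation p-value limited to n <= 9");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  double mx = mean(rx), my = mean(ry);
  double sx = 0.0, sy = 0.0;
  for (int i = 0; i < n; ++i) {
    sx += (rx[i] - mx) * (rx[i] - mx);
    sy += (ry[i] - my) * (ry[i] - my);
  }
  if (sx <= 0.0 || sy <= 0.0) stop("zero rank variance");
  double denom = std::sqrt(sx * sy);

  double obs = 0.0;
  for (int i = 0; i < n; ++i) obs += (rx[i] - mx) * (ry[i] - my);
  obs = std::fabs(obs / denom);

  long count = 0, total = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (rx[i] - mx) * (ry[idx[i]] - my);
    if (std::fabs(s / denom) >= obs - 1e-12) ++count;
    ++total;
  } while (std::next_permutation(idx.begin(), idx.end()));
  return (double)count / (double)total;
}
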