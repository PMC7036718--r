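#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "models.h"

using namespace Rcpp;

namespace {

// Dormand-Prince 5(4) tableau
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 35.0 / 384 - 5179.0 / 57600, e3 = 500.0 / 1113 - 7571.0 / 16695,
             e4 = 125.0 / 192 - 393.0 / 640, e5 = -2187.0 / 6784 + 92097.0 / 339200,
             e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

struct Rhs {
  int model, dim, pot_dim;
  const double* p;
  // full dimension including the quasi-potential accumulator (if any)
  int n() const { return dim + (pot_dim > 0 ? 1 : 0); }
  void operator()(const double* y, double u, double* dy) const {
    ghostmem::model_rhs(model, p, y, u, dy);
    if (pot_dim > 0) {
      double s = 0.0;
      for (int i = 0; i < pot_dim; ++i) s += dy[i] * dy[i];
      dy[dim] = -s; // dU/dt = -|f|^2 over the tracked coordinates
    }
  }
};

} // namespace

// Adaptive Dormand-Prince driver over piecewise-constant input segments.
// `breaks` are segment right endpoints (the last one must cover
// max(out_times)); `inputs[i]` is the input on (breaks[i-1], breaks[i]]
// (with an implicit left endpoint 0).  States are sampled exactly at
// `out_times`.  If pot_dim > 0, a quasi-potential accumulator U with
// dU/dt = -sum_{i < pot_dim} f_i^2 is appended as the last output column.
// [[Rcpp::export(name = ".ode_drive_cpp")]]
NumericMatrix ode_drive_cpp(int model, NumericVector params, NumericVector y0,
                            NumericVector breaks, NumericVector inputs,
                            NumericVector out_times,
                            double rtol = 1e-8, double atol = 1e-10,
                            int pot_dim = 0) {
  const int dim = ghostmem::model_dim(model);
  if ((int)y0.size() != dim)
    stop("init state has length %d, model expects %d", (int)y0.size(), dim);
  if (breaks.size() != inputs.size()) stop("breaks/inputs length mismatch");
  if (breaks.size() == 0) stop("need at least one input segment");
  Rhs f{model, dim, pot_dim, REAL(params)};
  const int n = f.n();
  const int nout = out_times.size();
  const double t_end = breaks[breaks.size() - 1];
  if (nout > 0 && out_times[nout - 1] > t_end + 1e-9)
    stop("output grid extends past the protocol horizon");

  std::vector<double> y(n, 0.0), ynew(n), yerr(n), k1(n), k2(n), k3(n), k4(n),
      k5(n), k6(n), k7(n), ytmp(n);
  for (int i = 0; i < dim; ++i) y[i] = y0[i];

  NumericMatrix out(nout, n);
  double t = 0.0;
  int iout = 0, iseg = 0;
  // time comparisons need a scale-aware epsilon: with t ~ 1e4 the gap to
  // an output time can fall below ulp(t) and a naive absolute tolerance
  // stalls the integration
  const double teps = std::max(1e-12, 4e-12 * std::max(1.0, t_end));
  auto record_due = [&]() {
    while (iout < nout && out_times[iout] <= t + teps) {
      for (int i = 0; i < n; ++i) out(iout, i) = y[i];
      ++iout;
    }
  };
  record_due();

  double h = 1e-2;
  const double hmin = 1e-13 * std::max(1.0, t_end);
  while (iout < nout || t < t_end - teps) {
    while (iseg < breaks.size() - 1 && t >= breaks[iseg] - teps) ++iseg;
    const double u = inputs[iseg];
    double t_stop = breaks[iseg];
    if (iout < nout) t_stop = std::min(t_stop, out_times[iout]);
    if (t_stop <= t + teps) { t = t_stop; record_due(); continue; }
    bool hit = false;
    double hs = h;
    if (t + hs >= t_stop - teps) { hs = t_stop - t; hit = true; }

    f(y.data(), u, k1.data());
    for (;;) {
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + hs * a21 * k1[i];
      f(ytmp.data(), u, k2.data());
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + hs * (a31 * k1[i] + a32 * k2[i]);
      f(ytmp.data(), u, k3.data());
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + hs * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      f(ytmp.data(), u, k4.data());
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + hs * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                               a54 * k4[i]);
      f(ytmp.data(), u, k5.data());
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + hs * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                               a64 * k4[i] + a65 * k5[i]);
      f(ytmp.data(), u, k6.data());
      for (int i = 0; i < n; ++i)
        ynew[i] = y[i] + hs * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                               b5 * k5[i] + b6 * k6[i]);
      f(ynew.data(), u, k7.data());
      double err = 0.0;
      for (int i = 0; i < n; ++i) {
        const double ei = hs * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                                e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                                 std::fabs(ynew[i]));
        err += (ei / sc) * (ei / sc);
      }
      err = std::sqrt(err / n);
      if (err <= 1.0) {
        t = hit ? t_stop : t + hs; // snap exactly onto stop points
        y.swap(ynew);
        // guard against integrator round-off pushing fractions negative
        // (fraction-based models only; the gradient test field is signed)
        for (int i = 0; model <= 3 && i < dim; ++i) {
          if (y[i] < 0.0) {
            if (y[i] > -1e-7) y[i] = 0.0;
            else stop("state %d went negative (%.3e) at t = %.6g", i + 1,
                      y[i], t);
          }
        }
        double fac = err > 0 ? 0.9 * std::pow(err, -0.2) : 5.0;
        fac = std::min(5.0, std::max(0.2, fac));
        if (!hit) h = hs * fac; else h = std::max(h, hs * fac);
        break;
      }
      hit = false;
      hs *= std::min(0.9, std::max(0.2, 0.9 * std::pow(err, -0.2)));
      if (hs < hmin)
        stop("integration failure (step underflow) at t = %.6g", t);
    }
    record_due();
  }
  return out;
}

// Single right-hand-side evaluation (used to cross-check the R-level
// derivative functions against the compiled model).
// [[Rcpp::export(name = ".model_rhs_cpp")]]
NumericVector model_rhs_cpp(int model, NumericVector params, NumericVector y,
                            double input) {
  const int dim = ghostmem::model_dim(model);
  if ((int)y.size() != dim) stop("state length mismatch");
  NumericVector dy(dim);
  ghostmem::model_rhs(model, REAL(params), REAL(y), input, REAL(dy));
  return dy;
}
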