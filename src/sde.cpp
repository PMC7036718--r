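#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "models.h"

using namespace Rcpp;

namespace {

// Multiplicative-noise amplitude sqrt(x(1-x)) per noisy coordinate.
// noise_mode 0: every state variable carries noise (toggle variant);
// noise_mode 1: only the first state (plasma-membrane Ra) is noisy.
inline void noise_amp(int mode, int dim, const double* y, double sigma,
                      double* g) {
  for (int i = 0; i < dim; ++i) g[i] = 0.0;
  const int upto = (mode == 0) ? dim : 1;
  for (int i = 0; i < upto; ++i) {
    const double v = y[i] * (1.0 - y[i]);
    g[i] = v > 0 ? sigma * std::sqrt(v) : 0.0;
  }
}

} // namespace

// Heun (predictor-corrector) integration of the Stratonovich SDE
// dy = f(y, u) dt + g(y) o dW, with piecewise-constant input and optional
// adaptive stepping: a step is rejected (and retried with dt/2, a fresh
// Wiener increment) when any state increment exceeds `inc_tol` or the state
// leaves [0,1]; after 10 consecutive accepted steps dt doubles, capped at
// dt_max.  States are clamped to [0,1] after acceptance and clamps counted.
// Uses the R RNG, so runs are reproducible under set.seed().
// [[Rcpp::export(name = ".sde_heun_cpp")]]
List sde_heun_cpp(int model, NumericVector params, NumericVector y0,
                  NumericVector breaks, NumericVector inputs,
                  NumericVector out_times, double sigma, int noise_mode,
                  bool adaptive, double dt0, double inc_tol = 0.01,
                  double dt_min = 1e-7, double dt_max = 1.0) {
  const int dim = ghostmem::model_dim(model);
  if ((int)y0.size() != dim) stop("init state length mismatch");
  if (breaks.size() != inputs.size()) stop("breaks/inputs length mismatch");
  const int nout = out_times.size();
  const double t_end = breaks[breaks.size() - 1];

  std::vector<double> y(y0.begin(), y0.end()), f0(dim), f1(dim), g0(dim),
      g1(dim), yp(dim), ynew(dim), dW(dim);
  NumericMatrix out(nout, dim);
  double t = 0.0, dt = dt0;
  int iout = 0, iseg = 0, accepts_in_row = 0;
  long n_steps = 0, n_rejected = 0, n_clamped = 0;
  const double teps = std::max(1e-12, 4e-12 * std::max(1.0, t_end));
  auto record_due = [&]() {
    while (iout < nout && out_times[iout] <= t + teps) {
      for (int i = 0; i < dim; ++i) out(iout, i) = y[i];
      ++iout;
    }
  };
  record_due();

  while (iout < nout || t < t_end - teps) {
    while (iseg < breaks.size() - 1 && t >= breaks[iseg] - teps) ++iseg;
    const double u = inputs[iseg];
    double t_stop = breaks[iseg];
    if (iout < nout) t_stop = std::min(t_stop, out_times[iout]);
    if (t_stop <= t + teps) { t = t_stop; record_due(); continue; }
    double hs = std::min(dt, t_stop - t);

    for (;;) {
      const bool hit = t + hs >= t_stop - teps;
      const double sq = std::sqrt(hs);
      for (int i = 0; i < dim; ++i) dW[i] = sq * norm_rand();
      ghostmem::model_rhs(model, REAL(params), y.data(), u, f0.data());
      noise_amp(noise_mode, dim, y.data(), sigma, g0.data());
      for (int i = 0; i < dim; ++i)
        yp[i] = y[i] + f0[i] * hs + g0[i] * dW[i];
      ghostmem::model_rhs(model, REAL(params), yp.data(), u, f1.data());
      noise_amp(noise_mode, dim, yp.data(), sigma, g1.data());
      bool ok = true;
      double maxinc = 0.0;
      for (int i = 0; i < dim; ++i) {
        ynew[i] = y[i] + 0.5 * (f0[i] + f1[i]) * hs +
                  0.5 * (g0[i] + g1[i]) * dW[i];
        maxinc = std::max(maxinc, std::fabs(ynew[i] - y[i]));
        if (ynew[i] < 0.0 || ynew[i] > 1.0) ok = false;
      }
      ++n_steps;
      // a step that would leave [0,1] or move too far is retried with
      // dt/2 and a fresh increment; at the step-size floor it is accepted
      // with clamping (counted)
      const bool at_floor = hs <= dt_min * (1.0 + 1e-9);
      if (!adaptive || (ok && maxinc <= inc_tol) || at_floor) {
        t = hit ? t_stop : t + hs;
        for (int i = 0; i < dim; ++i) {
          double v = ynew[i];
          if (v < 0.0) { v = 0.0; ++n_clamped; }
          if (v > 1.0) { v = 1.0; ++n_clamped; }
          y[i] = v;
        }
        if (adaptive && ++accepts_in_row >= 10) {
          dt = std::min(dt * 2.0, dt_max);
          accepts_in_row = 0;
        }
        break;
      }
      ++n_rejected;
      accepts_in_row = 0;
      hs = std::max(0.5 * hs, dt_min);
      dt = hs;
    }
    record_due();
  }
  return List::create(_["states"] = out, _["n_steps"] = (double)n_steps,
                      _["n_rejected"] = (double)n_rejected,
                      _["n_clamped"] = (double)n_clamped);
}
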