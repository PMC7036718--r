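#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
#include "models.h"

using namespace Rcpp;

namespace {

struct CellGrid {
  int m;
  double cs, L;
  std::vector<int> head, next;
  CellGrid(int n, double L_, double sigma) : L(L_) {
    // cell size >= sigma so a 3x3 block covers the interaction disc;
    // capped so the grid stays small enough to clear cheaply each step
    m = std::max(3, std::min((int)std::floor(L_ / sigma), 48));
    cs = L_ / m;
    head.assign(m * m, -1);
    next.assign(n, -1);
  }
  int cell_of(double x, double y) const {
    int cx = (int)(x / cs), cy = (int)(y / cs);
    if (cx >= m) cx = m - 1;
    if (cy >= m) cy = m - 1;
    return cy * m + cx;
  }
  void build(const std::vector<double>& x, const std::vector<double>& y) {
    std::fill(head.begin(), head.end(), -1);
    for (int i = (int)x.size() - 1; i >= 0; --i) {
      const int c = cell_of(x[i], y[i]);
      next[i] = head[c];
      head[c] = i;
    }
  }
};

inline double pdist2(double dx, double dy, double L) {
  dx = std::fabs(dx); if (dx > 0.5 * L) dx = L - dx;
  dy = std::fabs(dy); if (dy > 0.5 * L) dy = L - dy;
  return dx * dx + dy * dy;
}

inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  return (x >= L) ? 0.0 : x; // guard against round-off at the boundary
}

} // namespace

// Doi-method reaction-diffusion simulation of the receptor/phosphatase
// toggle switch on a periodic 2D membrane.  Molecules 0..nR-1 are receptors
// (R), nR..nR+nP-1 are phosphatases (P).  Bimolecular channels (per-step
// probability 1 - (1 - rate*dt)^n over the n eligible partners within the
// interaction radius, states updated synchronously from the pre-step
// configuration):
//   Ri + Ri  -> Ri + Ra   (a1t, autonomous activation)
//   Ra + Ri  -> 2 Ra      (a2t, autocatalytic propagation; logged for R0)
//   Pa + Ra  -> Pa + Ri   (gt,  receptor deactivation)
//   Ra + Pa  -> Ra + Pi   (bt,  phosphatase inhibition)
// Unimolecular: Pi -> Pa (k1t), Pa -> Pi (k2t).
// Returns activity time series, activation/deactivation event logs within
// [log_t0, log_t1], and optional position snapshots.
// [[Rcpp::export(name = ".particle_sim_cpp")]]
List particle_sim_cpp(int nR, int nP, double L, double D, double sigma,
                      double dt, int nsteps, double a1t, double a2t,
                      double bt, double gt, double k1t, double k2t,
                      double fracRa0, double fracPa0, int record_every,
                      double log_t0, double log_t1, int snapshot_every = 0) {
  if (a1t * dt > 1 || a2t * dt > 1 || bt * dt > 1 || gt * dt > 1 ||
      k1t * dt > 1 || k2t * dt > 1)
    stop("a per-step reaction probability exceeds 1; reduce dt or the rates");
  if (4.0 * std::sqrt(2.0 * D * dt) > sigma)
    stop("detection guarantee violated: 4*sqrt(2*D*dt) > sigma");

  const int n = nR + nP;
  std::vector<double> x(n), y(n);
  std::vector<char> act(n), act0(n);
  for (int i = 0; i < n; ++i) {
    x[i] = unif_rand() * L;
    y[i] = unif_rand() * L;
    act[i] = (i < nR) ? (unif_rand() < fracRa0) : (unif_rand() < fracPa0);
  }
  const double sig2 = sigma * sigma, sd = std::sqrt(2.0 * D * dt);
  const double q1 = 1.0 - a1t * dt, q2 = 1.0 - a2t * dt,
               qb = 1.0 - bt * dt, qg = 1.0 - gt * dt;

  CellGrid grid(n, L, sigma);
  std::vector<double> act_time(nR, 0.0); // activation time of active R
  std::vector<int> offspring(nR, 0);
  std::vector<double> ev_t, de_t, de_life;
  std::vector<int> ev_src, ev_dst, de_id, de_off;
  std::vector<int> ra_nb;
  ra_nb.reserve(32);

  const int nrec = nsteps / record_every + 1;
  NumericMatrix counts(nrec, 3);
  int irec = 0;
  List snapshots;
  auto record = [&](int step) {
    int cRa = 0, cPa = 0;
    for (int i = 0; i < nR; ++i) cRa += act[i];
    for (int i = nR; i < n; ++i) cPa += act[i];
    counts(irec, 0) = step * dt;
    counts(irec, 1) = cRa;
    counts(irec, 2) = cPa;
    ++irec;
  };
  record(0);

  for (int step = 1; step <= nsteps; ++step) {
    const double t = step * dt;
    const bool logging = (t >= log_t0 && t <= log_t1);
    for (int i = 0; i < n; ++i) {
      x[i] = wrap(x[i] + sd * norm_rand(), L);
      y[i] = wrap(y[i] + sd * norm_rand(), L);
    }
    grid.build(x, y);
    std::copy(act.begin(), act.end(), act0.begin());

    for (int i = 0; i < n; ++i) {
      int nRa = 0, nRi = 0, nPa = 0;
      const bool isR = i < nR;
      const bool need_ids = isR && !act0[i] && a2t > 0;
      if (need_ids) ra_nb.clear();
      const int cx = (int)(x[i] / grid.cs) % grid.m,
                cy = (int)(y[i] / grid.cs) % grid.m;
      for (int ox = -1; ox <= 1; ++ox) {
        for (int oy = -1; oy <= 1; ++oy) {
          const int c = ((cy + oy + grid.m) % grid.m) * grid.m +
                        ((cx + ox + grid.m) % grid.m);
          for (int j = grid.head[c]; j >= 0; j = grid.next[j]) {
            if (j == i) continue;
            if (pdist2(x[i] - x[j], y[i] - y[j], L) > sig2) continue;
            if (j < nR) {
              if (act0[j]) {
                ++nRa;
                if (need_ids) ra_nb.push_back(j);
              } else {
                ++nRi;
              }
            } else if (act0[j]) {
              ++nPa;
            }
          }
        }
      }
      if (isR) {
        if (!act0[i]) { // susceptible receptor: activation channels
          const double p2 = 1.0 - std::pow(q2, nRa);
          const bool fire2 = p2 > 0 && unif_rand() < p2;
          const double p1 = 1.0 - std::pow(q1, nRi);
          const bool fire1 = !fire2 && p1 > 0 && unif_rand() < p1;
          if (fire1 || fire2) {
            act[i] = 1;
            act_time[i] = t;
            offspring[i] = 0;
            int src = -1;
            if (fire2) {
              src = ra_nb[(int)(unif_rand() * ra_nb.size()) %
                          (int)ra_nb.size()];
              ++offspring[src];
            }
            if (logging) {
              ev_t.push_back(t);
              ev_src.push_back(src);
              ev_dst.push_back(i);
            }
          }
        } else { // active receptor: deactivation by active phosphatase
          const double p = 1.0 - std::pow(qg, nPa);
          if (p > 0 && unif_rand() < p) {
            act[i] = 0;
            if (logging) {
              de_t.push_back(t);
              de_id.push_back(i);
              de_off.push_back(offspring[i]);
              de_life.push_back(t - act_time[i]);
            }
          }
        }
      } else {
        if (!act0[i]) { // inactive phosphatase: spontaneous activation
          if (unif_rand() < k1t * dt) act[i] = 1;
        } else { // active phosphatase: spontaneous + receptor-driven loss
          const double p = 1.0 - (1.0 - k2t * dt) * std::pow(qb, nRa);
          if (unif_rand() < p) act[i] = 0;
        }
      }
    }
    if (step % record_every == 0) record(step);
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      NumericMatrix snap(n, 4);
      for (int i = 0; i < n; ++i) {
        snap(i, 0) = x[i];
        snap(i, 1) = y[i];
        snap(i, 2) = (i < nR) ? 1 : 2;
        snap(i, 3) = act[i];
      }
      snapshots.push_back(snap);
    }
  }

  return List::create(
      _["counts"] = counts(Range(0, irec - 1), _),
      _["activations"] = DataFrame::create(_["time"] = ev_t,
                                           _["activator"] = ev_src,
                                           _["activated"] = ev_dst),
      _["deactivations"] = DataFrame::create(_["time"] = de_t,
                                             _["id"] = de_id,
                                             _["offspring"] = de_off,
                                             _["lifetime"] = de_life),
      _["snapshots"] = snapshots);
}
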