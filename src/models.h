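#pragma once
#include <cmath>
#include <stdexcept>

namespace ghostmem {

// Model ids, shared between the ODE and SDE drivers.  Parameter vector
// layouts are fixed and mirrored by the R wrappers (see R/params.R):
//
//   0 toggle, dynamic ligand   y = (Ra, Pa, LRa),   input u = L_T
//   1 toggle, LRa as parameter y = (Ra, Pa),        input u = LRa
//   2 compartment (7 species)  y = (RaPM, RiPM, Pa, LRaPM, RaE, RiE, LRiE),
//                              input u = L_T
//   3 exponential decay        y = Ra,              input u = I (0/1)
//   4 gradient test field      y = (x, y), U = a (x^2-1)^2 + b y^2 + c x y
//
// Toggle parameter layout: (alpha1, alpha2, alpha3, betaDNF_hat,
//   gammaDNF_hat, k1, k21, kR, kon, koff).
// Compartment layout: (alpha1, alpha2, alpha3, gammaDNF, gammaNF, gammaNR,
//   betaDNF, k1, k21, kin, kini, krec, kdeg, RT, PDNFT, PNFT, PNRT,
//   kon, koff, RT_asymp, sat, dynamic_krec_flag).
// Decay layout: (alpha, beta, RT).
// Gradient layout: (a, b, c).

inline int model_dim(int model) {
  switch (model) {
  case 0: return 3;
  case 1: return 2;
  case 2: return 7;
  case 3: return 1;
  case 4: return 2;
  default: throw std::invalid_argument("unknown model id");
  }
}

// Recycling-rate multiplier for the self-organization law; the multiplier
// (RT - RT_asymp) / (RT (1 - LRiE) - RT_asymp) is capped at `sat`, and a
// non-positive denominator falls to the cap.
inline double dyn_recycling_mult(double LRiE, double RT, double RTa,
                                 double sat) {
  const double den = RT * (1.0 - LRiE) - RTa;
  if (den <= 0.0) return sat;
  const double m = (RT - RTa) / den;
  return (m > sat) ? sat : m;
}

inline void model_rhs(int model, const double* p, const double* y, double u,
                      double* dy) {
  switch (model) {
  case 0: { // toggle switch, ligand binding explicit
    const double a1 = p[0], a2 = p[1], a3 = p[2], bh = p[3], gh = p[4],
                 k1 = p[5], k21 = p[6], kR = p[7], kon = p[8], koff = p[9];
    const double Ra = y[0], Pa = y[1], LRa = y[2];
    const double Ri = 1.0 - Ra - LRa;
    dy[0] = kR * (Ri * (a1 * Ri + a2 * Ra + a3 * LRa) - gh * Pa * Ra)
            - kon * Ra * u + 0.5 * koff * LRa;
    dy[1] = k1 * ((1.0 - Pa) - k21 * Pa - bh * Pa * (Ra + LRa));
    dy[2] = kon * (Ra + Ri) * u - koff * LRa;
    break;
  }
  case 1: { // toggle switch, LRa held constant (bifurcation mode)
    const double a1 = p[0], a2 = p[1], a3 = p[2], bh = p[3], gh = p[4],
                 k1 = p[5], k21 = p[6], kR = p[7];
    const double Ra = y[0], Pa = y[1];
    const double Ri = 1.0 - Ra;
    dy[0] = kR * (Ri * (a1 * Ri + a2 * Ra + a3 * u) - gh * Pa * Ra);
    dy[1] = k1 * ((1.0 - Pa) - k21 * Pa - bh * Pa * (Ra + u));
    break;
  }
  case 2: { // two-compartment trafficking model
    const double a1 = p[0], a2 = p[1], a3 = p[2], gDNF = p[3], gNF = p[4],
                 gNR = p[5], bDNF = p[6], k1 = p[7], k21 = p[8], kin = p[9],
                 kini = p[10], krec = p[11], kdeg = p[12], RT = p[13],
                 PDNFT = p[14], PNFT = p[15], PNRT = p[16], kon = p[17],
                 koff = p[18], RTa = p[19], sat = p[20];
    const bool dyn = p[21] > 0.5;
    const double RaPM = y[0], RiPM = y[1], Pa = y[2], LRaPM = y[3],
                 RaE = y[4], RiE = y[5], LRiE = y[6];
    const double kr = dyn ? krec * dyn_recycling_mult(LRiE, RT, RTa, sat)
                          : krec;
    const double act = RT * RiPM * (a1 * RiPM + a2 * RaPM + a3 * LRaPM);
    const double dephos = gDNF * PDNFT * Pa * RaPM + gNR * PNRT * RaPM;
    dy[0] = act - dephos - kin * RaPM - kon * RaPM * u + 0.5 * koff * LRaPM;
    dy[1] = -act + dephos - kini * kin * RiPM + kr * RiE - kon * RiPM * u
            + 0.5 * koff * LRaPM;
    dy[2] = k1 * ((1.0 - Pa) - k21 * Pa - bDNF * Pa * RT * (RaPM + LRaPM));
    dy[3] = kon * (RaPM + RiPM) * u - koff * LRaPM - kdeg * kin * LRaPM;
    dy[4] = kin * RaPM - gNF * PNFT * RaE;
    dy[5] = kini * kin * RiPM + gNF * PNFT * RaE - kr * RiE;
    dy[6] = kdeg * kin * LRaPM;
    break;
  }
  case 3: { // exponential decay baseline
    dy[0] = u * p[0] * (p[2] - y[0]) - p[1] * y[0];
    break;
  }
  case 4: { // analytic gradient system (quasi-potential oracle)
    const double a = p[0], b = p[1], c = p[2];
    dy[0] = -(4.0 * a * y[0] * (y[0] * y[0] - 1.0) + c * y[1]);
    dy[1] = -(2.0 * b * y[1] + c * y[0]);
    break;
  }
  default: throw std::invalid_argument("unknown model id");
  }
}

} // namespace ghostmem
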