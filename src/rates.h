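#ifndef SPHEROIDR_RATES_H
#define SPHEROIDR_RATES_H

#include <cmath>

// Per-capita rate laws shared by the event engine. The nutrient
// concentration c is non-dimensional, c in [0, 1]; rates are h^-1.
struct RateParams {
  double Rr_max, Ry, Rg;
  double d_max, d_min, m_max, m_min;
  double eta1, eta2, eta3;
  double c_a, c_m, c_d;
};

inline double hill_term(double c, double K, double eta) {
  if (c <= 0.0) return 0.0;
  double cn = std::pow(c, eta);
  return cn / (std::pow(K, eta) + cn);
}

// red (G1) -> yellow (eS): nutrient-gated commitment to the cycle
inline double rate_r2y(double c, const RateParams& p) {
  return p.Rr_max * hill_term(c, p.c_a, p.eta1);
}

// migration rate, bounded in [m_min, m_max)
inline double rate_mig(double c, const RateParams& p) {
  return (p.m_max - p.m_min) * hill_term(c, p.c_m, p.eta2) + p.m_min;
}

// death rate, bounded in (d_min, d_max]; decreasing in c
inline double rate_dth(double c, const RateParams& p) {
  return (p.d_max - p.d_min) * (1.0 - hill_term(c, p.c_d, p.eta3)) + p.d_min;
}

#endif
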