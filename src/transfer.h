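#ifndef ADEXBRAIN_TRANSFER_H
#define ADEXBRAIN_TRANSFER_H

#include <cmath>

// Semi-analytic population transfer function for conductance-based AdEx
// populations. All quantities in internal units: ms, mV, nS, pF, pA, kHz.
//
// Rate floor: the spectral moments sigma_V / tau_V are undefined at exactly
// zero presynaptic rate; a tiny floor keeps them finite without affecting
// any rate of physiological size.

namespace adexbrain {

struct TFParams {
  double gL;     // leak conductance, nS
  double Cm;     // capacitance, pF
  double EL;     // leak reversal, mV
  double Ee;     // excitatory synaptic reversal, mV
  double Ei;     // inhibitory synaptic reversal, mV
  double Qe;     // excitatory quantal conductance, nS
  double Qi;     // inhibitory quantal conductance, nS
  double taue;   // excitatory synaptic decay, ms
  double taui;   // inhibitory synaptic decay, ms
  double Ke;     // excitatory synapses per neuron
  double Ki;     // inhibitory synapses per neuron
  double Trefr;  // refractory period, ms (rate ceiling = 1/Trefr)
  double P[10];  // effective-threshold polynomial coefficients, mV
};

struct VoltageMoments {
  double muGe, muGi, muG;  // conductances, nS
  double muV;              // mean membrane potential, mV
  double sV;               // SD of membrane potential, mV
  double Tv;               // autocorrelation time, ms
};

// Rescaling constants of the threshold polynomial (fixed normalization of
// the fluctuation-driven regime; coefficients are fitted on top of these).
const double MUV0 = -60.0, DMUV0 = 10.0;
const double SV0 = 4.0, DSV0 = 6.0;
const double TVN0 = 0.5, DTVN0 = 1.0;
const double RATE_FLOOR = 1e-9;  // kHz

inline VoltageMoments voltage_moments(double fe, double fi, double W,
                                      const TFParams& p) {
  if (fe < RATE_FLOOR) fe = RATE_FLOOR;
  if (fi < RATE_FLOOR) fi = RATE_FLOOR;
  VoltageMoments m;
  m.muGe = fe * p.Ke * p.taue * p.Qe;
  m.muGi = fi * p.Ki * p.taui * p.Qi;
  m.muG = m.muGe + m.muGi + p.gL;
  m.muV = (m.muGe * p.Ee + m.muGi * p.Ei + p.gL * p.EL - W) / m.muG;
  const double Tm = p.Cm / m.muG;
  const double Ue = (p.Qe / m.muG) * (p.Ee - m.muV);
  const double Ui = (p.Qi / m.muG) * (p.Ei - m.muV);
  const double he = fe * p.Ke * (Ue * p.taue) * (Ue * p.taue);
  const double hi = fi * p.Ki * (Ui * p.taui) * (Ui * p.taui);
  const double se = he / (Tm + p.taue);
  const double si = hi / (Tm + p.taui);
  m.sV = std::sqrt(0.5 * (se + si));
  m.Tv = (he + hi) / (se + si);
  return m;
}

inline double threshold_poly(const VoltageMoments& m, const TFParams& p) {
  const double x1 = (m.muV - MUV0) / DMUV0;
  const double x2 = (m.sV - SV0) / DSV0;
  const double x3 = (m.Tv * p.gL / p.Cm - TVN0) / DTVN0;
  const double* P = p.P;
  return P[0] + P[1] * x1 + P[2] * x2 + P[3] * x3 + P[4] * x1 * x1 +
         P[5] * x1 * x2 + P[6] * x1 * x3 + P[7] * x2 * x2 + P[8] * x2 * x3 +
         P[9] * x3 * x3;
}

// Output rate in kHz, clipped to [0, 1/Trefr].
inline double tf_rate(double fe, double fi, double W, const TFParams& p) {
  const VoltageMoments m = voltage_moments(fe, fi, W, p);
  const double vthre = threshold_poly(m, p);
  double out;
  if (m.sV < 1e-12) {
    out = (m.muV > vthre) ? 1.0 / p.Trefr : 0.0;
  } else {
    out = 0.5 / m.Tv * std::erfc((vthre - m.muV) / (std::sqrt(2.0) * m.sV));
  }
  if (out < 0.0) out = 0.0;
  const double cap = 1.0 / p.Trefr;
  if (out > cap) out = cap;
  return out;
}

}  // namespace adexbrain

#endif
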