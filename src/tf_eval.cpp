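#include <Rcpp.h>
#include "transfer.h"
using namespace Rcpp;
using adexbrain::TFParams;

TFParams tf_from_list(List tfp) {
  TFParams p;
  p.gL = tfp["g_L"]; p.Cm = tfp["c_m"]; p.EL = tfp["E_L"];
  p.Ee = tfp["E_e"]; p.Ei = tfp["E_i"];
  p.Qe = tfp["Q_e"]; p.Qi = tfp["Q_i"];
  p.taue = tfp["u_e"]; p.taui = tfp["u_i"];
  p.Ke = tfp["K_e"]; p.Ki = tfp["K_i"];
  p.Trefr = tfp["T_refr"];
  NumericVector P = tfp["P"];
  for (int i = 0; i < 10; ++i) p.P[i] = P[i];
  return p;
}

// Vectorized transfer-function evaluation; rates in kHz in and out.
// [[Rcpp::export]]
NumericVector tf_rate_cpp(NumericVector fe, NumericVector fi, NumericVector W,
                          List tfp) {
  const TFParams p = tf_from_list(tfp);
  const int n = fe.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = adexbrain::tf_rate(fe[i], fi[i], W[i], p);
  return out;
}

// Membrane-potential moments (muGe, muGi, muG, muV, sigmaV, tauV) per input.
// [[Rcpp::export]]
DataFrame voltage_moments_cpp(NumericVector fe, NumericVector fi,
                              NumericVector W, List tfp) {
  const TFParams p = tf_from_list(tfp);
  const int n = fe.size();
  NumericVector muGe(n), muGi(n), muG(n), muV(n), sV(n), Tv(n);
  for (int i = 0; i < n; ++i) {
    adexbrain::VoltageMoments m =
        adexbrain::voltage_moments(fe[i], fi[i], W[i], p);
    muGe[i] = m.muGe; muGi[i] = m.muGi; muG[i] = m.muG;
    muV[i] = m.muV; sV[i] = m.sV; Tv[i] = m.Tv;
  }
  return DataFrame::create(_["mu_Ge"] = muGe, _["mu_Gi"] = muGi,
                           _["mu_G"] = muG, _["mu_V"] = muV,
                           _["sigma_V"] = sV, _["tau_V"] = Tv);
}
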