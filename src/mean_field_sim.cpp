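#include <Rcpp.h>
#include "transfer.h"
using namespace Rcpp;
using adexbrain::TFParams;
using adexbrain::tf_rate;

TFParams tf_from_list(List tfp);

namespace {

// Transfer functions with the single-region input convention:
// Fe(nu_e + aff + drive, nu_i; W), Fi(nu_e + aff, nu_i; 0).
struct RegionTF {
  TFParams e, i;
  double Fe(double fe_in, double fi, double W) const {
    return tf_rate(fe_in < 0 ? 0 : fe_in, fi < 0 ? 0 : fi, W, e);
  }
  double Fi(double fe_in, double fi) const {
    return tf_rate(fe_in < 0 ? 0 : fe_in, fi < 0 ? 0 : fi, 0.0, i);
  }
};

const double DH = 1e-4;  // finite-difference step, kHz (0.1 Hz)

struct Derivs {
  double Fe, Fi;
  double dFe_e, dFe_i, dFi_e, dFi_i;
  double d2Fe_ee, d2Fe_ei, d2Fe_ii, d2Fi_ee, d2Fi_ei, d2Fi_ii;
};

// Central finite differences of both TFs w.r.t. the state rates, at fixed
// additive offsets (afferent/drive enter the excitatory argument only).
Derivs tf_derivs(const RegionTF& tf, double fe, double fi, double offE,
                 double offI, double W) {
  Derivs d;
  const double h = DH;
  const double xe = fe + offE, xi = fe + offI;
  d.Fe = tf.Fe(xe, fi, W);
  d.Fi = tf.Fi(xi, fi);
  const double Fe_pe = tf.Fe(xe + h, fi, W), Fe_me = tf.Fe(xe - h, fi, W);
  const double Fe_pi = tf.Fe(xe, fi + h, W), Fe_mi = tf.Fe(xe, fi - h, W);
  const double Fi_pe = tf.Fi(xi + h, fi), Fi_me = tf.Fi(xi - h, fi);
  const double Fi_pi = tf.Fi(xi, fi + h), Fi_mi = tf.Fi(xi, fi - h);
  d.dFe_e = (Fe_pe - Fe_me) / (2 * h);
  d.dFe_i = (Fe_pi - Fe_mi) / (2 * h);
  d.dFi_e = (Fi_pe - Fi_me) / (2 * h);
  d.dFi_i = (Fi_pi - Fi_mi) / (2 * h);
  d.d2Fe_ee = (Fe_pe - 2 * d.Fe + Fe_me) / (h * h);
  d.d2Fe_ii = (Fe_pi - 2 * d.Fe + Fe_mi) / (h * h);
  d.d2Fi_ee = (Fi_pe - 2 * d.Fi + Fi_me) / (h * h);
  d.d2Fi_ii = (Fi_pi - 2 * d.Fi + Fi_mi) / (h * h);
  d.d2Fe_ei = (tf.Fe(xe + h, fi + h, W) - tf.Fe(xe + h, fi - h, W) -
               tf.Fe(xe - h, fi + h, W) + tf.Fe(xe - h, fi - h, W)) /
              (4 * h * h);
  d.d2Fi_ei = (tf.Fi(xi + h, fi + h) - tf.Fi(xi + h, fi - h) -
               tf.Fi(xi - h, fi + h) + tf.Fi(xi - h, fi - h)) /
              (4 * h * h);
  return d;
}

struct State {
  double fe, fi, W, cee, cei, cii;
};

State rhs(const RegionTF& tf, const State& s, double drive, double aff,
          double T, double Ne, double Ni, double a, double b, double uw,
          double EL, int order, bool drive_to_i) {
  State ds;
  const double offE = aff + drive, offI = aff + (drive_to_i ? drive : 0.0);
  if (order == 1) {
    const double Fe = tf.Fe(s.fe + offE, s.fi, s.W);
    const double Fi = tf.Fi(s.fe + offI, s.fi);
    ds.fe = (Fe - s.fe) / T;
    ds.fi = (Fi - s.fi) / T;
    ds.cee = ds.cei = ds.cii = 0.0;
    adexbrain::VoltageMoments m =
        adexbrain::voltage_moments(s.fe, s.fi, s.W, tf.e);
    ds.W = -s.W / uw + b * s.fe + a * (m.muV - EL);
    return ds;
  }
  const Derivs d = tf_derivs(tf, s.fe, s.fi, offE, offI, s.W);
  ds.fe = (d.Fe - s.fe +
           0.5 * (s.cee * d.d2Fe_ee + 2 * s.cei * d.d2Fe_ei +
                  s.cii * d.d2Fe_ii)) /
          T;
  ds.fi = (d.Fi - s.fi +
           0.5 * (s.cee * d.d2Fi_ee + 2 * s.cei * d.d2Fi_ei +
                  s.cii * d.d2Fi_ii)) /
          T;
  ds.cee = (d.Fe * (1.0 / T - d.Fe) / Ne + (d.Fe - s.fe) * (d.Fe - s.fe) +
            2 * (d.dFe_e * s.cee + d.dFe_i * s.cei) - 2 * s.cee) /
           T;
  ds.cei = ((d.Fe - s.fe) * (d.Fi - s.fi) + d.dFe_e * s.cei +
            d.dFe_i * s.cii + d.dFi_e * s.cee + d.dFi_i * s.cei -
            2 * s.cei) /
           T;
  ds.cii = (d.Fi * (1.0 / T - d.Fi) / Ni + (d.Fi - s.fi) * (d.Fi - s.fi) +
            2 * (d.dFi_e * s.cei + d.dFi_i * s.cii) - 2 * s.cii) /
           T;
  adexbrain::VoltageMoments m =
      adexbrain::voltage_moments(s.fe, s.fi, s.W, tf.e);
  ds.W = -s.W / uw + b * s.fe + a * (m.muV - EL);
  return ds;
}

// Physical bounds: population rates live in [0, 1/T_refr]; the variance of
// a rate bounded by 200 Hz (0.2 kHz) cannot exceed (0.1 kHz)^2; the cross
// covariance obeys Cauchy-Schwarz. The Master Equation can overshoot these
// transiently (it is derived for small fluctuations), so they are enforced
// after every stage.
void clipState(State& s, double rate_cap) {
  const double var_cap = 0.25 * rate_cap * rate_cap;
  if (s.fe < 0) s.fe = 0;
  if (s.fi < 0) s.fi = 0;
  if (s.fe > rate_cap) s.fe = rate_cap;
  if (s.fi > rate_cap) s.fi = rate_cap;
  if (s.cee < 0) s.cee = 0;
  if (s.cii < 0) s.cii = 0;
  if (s.cee > var_cap) s.cee = var_cap;
  if (s.cii > var_cap) s.cii = var_cap;
  const double bound = std::sqrt(s.cee * s.cii);
  if (s.cei > bound) s.cei = bound;
  if (s.cei < -bound) s.cei = -bound;
}

}  // namespace

// Heun (stochastic) integration of the single-region mean field, first or
// second order. OU drive updated by its exact discretization; rates in kHz.
// [[Rcpp::export]]
List sim_mean_field_cpp(List tfe, List tfi, double T, double Ne, double Ni,
                        double a, double b, double uw, double EL,
                        double ou_mean, double ou_sd, double ou_tau,
                        double nu_aff, double duration, double dt, int order,
                        int record_every, double fe0, double fi0, double W0,
                        NumericVector c0, bool drive_to_i) {
  RegionTF tf;
  tf.e = tf_from_list(tfe);
  tf.i = tf_from_list(tfi);
  const int nsteps = (int)std::lround(duration / dt);
  const double ou_dec = std::exp(-dt / ou_tau);
  const double ou_noise = ou_sd * std::sqrt(1.0 - ou_dec * ou_dec);

  State s;
  s.fe = fe0; s.fi = fi0; s.W = W0;
  s.cee = c0[0]; s.cei = c0[1]; s.cii = c0[2];
  double drive = ou_mean;

  const int nrec = nsteps / record_every + 1;
  NumericVector t_out(nrec), fe_out(nrec), fi_out(nrec), W_out(nrec),
      cee_out(nrec), cei_out(nrec), cii_out(nrec), drv_out(nrec);
  int irec = 0;

  for (int step = 0; step <= nsteps; ++step) {
    if (step % record_every == 0 && irec < nrec) {
      t_out[irec] = step * dt;
      fe_out[irec] = s.fe; fi_out[irec] = s.fi; W_out[irec] = s.W;
      cee_out[irec] = s.cee; cei_out[irec] = s.cei; cii_out[irec] = s.cii;
      drv_out[irec] = drive;
      ++irec;
    }
    if (step == nsteps) break;
    const double drive_next =
        ou_mean + (drive - ou_mean) * ou_dec + ou_noise * norm_rand();
    const State k1 = rhs(tf, s, drive, nu_aff, T, Ne, Ni, a, b, uw, EL,
                         order, drive_to_i);
    State sp = s;
    sp.fe += dt * k1.fe; sp.fi += dt * k1.fi; sp.W += dt * k1.W;
    sp.cee += dt * k1.cee; sp.cei += dt * k1.cei; sp.cii += dt * k1.cii;
    clipState(sp, 1.0 / tf.e.Trefr);
    const State k2 = rhs(tf, sp, drive_next, nu_aff, T, Ne, Ni, a, b, uw,
                         EL, order, drive_to_i);
    s.fe += 0.5 * dt * (k1.fe + k2.fe);
    s.fi += 0.5 * dt * (k1.fi + k2.fi);
    s.W += 0.5 * dt * (k1.W + k2.W);
    s.cee += 0.5 * dt * (k1.cee + k2.cee);
    s.cei += 0.5 * dt * (k1.cei + k2.cei);
    s.cii += 0.5 * dt * (k1.cii + k2.cii);
    clipState(s, 1.0 / tf.e.Trefr);
    drive = drive_next;
    if (!std::isfinite(s.fe) || !std::isfinite(s.fi) || !std::isfinite(s.W))
      stop("mean-field state diverged at t=%f ms (last good state recorded)",
           step * dt);
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = t_out, _["nu_e"] = fe_out,
                      _["nu_i"] = fi_out, _["W"] = W_out,
                      _["c_ee"] = cee_out, _["c_ei"] = cei_out,
                      _["c_ii"] = cii_out, _["drive"] = drv_out);
}
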