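#include <Rcpp.h>
#include "transfer.h"
#include <vector>
using namespace Rcpp;
using adexbrain::TFParams;
using adexbrain::tf_rate;

TFParams tf_from_list(List tfp);

// Network of first-order mean-field regions coupled by the connectome with
// axonal delays (ring-buffer history of excitatory rates). Per region:
//   T dnu_e(k)/dt = Fe[nu_input(k) + nu_aff, nu_i(k); W(k)] - nu_e(k)
//   T dnu_i(k)/dt = Fi[nu_input(k) + nu_aff, nu_i(k); 0]    - nu_i(k)
//   dW(k)/dt      = -W(k)/u_w + b nu_e(k) + a (mu_V(k) - E_L)
// with nu_input(k) = drive_k(t) + nu_e(k,t) + S * sum_{j!=k} C_jk
// nu_e(j, t - d_jk) (self-coupling C_kk = 1 unscaled by S). A square-wave
// stimulus adds its amplitude to the excitatory-population TF input of the
// target region. Per-region OU drives share one seeded RNG stream.
// [[Rcpp::export]]
List sim_brain_cpp(List tfe, List tfi, double T, double a, double b,
                   double uw, double EL, NumericMatrix weights,
                   IntegerMatrix delay_steps, double S, double ou_mean,
                   double ou_sd, double ou_tau, double nu_aff,
                   double duration, double dt, int record_every,
                   NumericVector fe0, NumericVector fi0, NumericVector W0,
                   int stim_target, double stim_amp, double stim_onset,
                   double stim_dur) {
  const int n = weights.nrow();
  if (weights.ncol() != n || delay_steps.nrow() != n || delay_steps.ncol() != n)
    stop("weights/delays must be square matrices of matching size");
  TFParams pe = tf_from_list(tfe), pi = tf_from_list(tfi);
  const int nsteps = (int)std::lround(duration / dt);
  const double ou_dec = std::exp(-dt / ou_tau);
  const double ou_noise = ou_sd * std::sqrt(1.0 - ou_dec * ou_dec);

  int maxlag = 0;
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < n; ++k)
      if (delay_steps(j, k) > maxlag) maxlag = delay_steps(j, k);
  const int L = maxlag + 2;

  std::vector<double> fe(fe0.begin(), fe0.end()),
      fi(fi0.begin(), fi0.end()), W(W0.begin(), W0.end());
  std::vector<double> drive(n, ou_mean), drive_next(n);
  // hist[j*L + (step mod L)] = nu_e(j) at that step; warm-up with fe0.
  std::vector<double> hist((size_t)n * L);
  for (int j = 0; j < n; ++j)
    for (int c = 0; c < L; ++c) hist[(size_t)j * L + c] = fe0[j];

  const int nrec = nsteps / record_every + 1;
  NumericMatrix fe_out(nrec, n), fi_out(nrec, n), W_out(nrec, n);
  NumericVector t_out(nrec);
  int irec = 0;

  std::vector<double> coup(n), coup_next(n), fe_pred(n), fi_pred(n),
      W_pred(n), k1fe(n), k1fi(n), k1W(n);

  for (int step = 0; step <= nsteps; ++step) {
    const double t = step * dt;
    if (step % record_every == 0 && irec < nrec) {
      for (int k = 0; k < n; ++k) {
        fe_out(irec, k) = fe[k];
        fi_out(irec, k) = fi[k];
        W_out(irec, k) = W[k];
      }
      t_out[irec++] = t;
    }
    if (step == nsteps) break;

    // store current nu_e into history at slot (step mod L)
    const int slot = step % L;
    for (int j = 0; j < n; ++j) hist[(size_t)j * L + slot] = fe[j];

    for (int k = 0; k < n; ++k)
      drive_next[k] =
          ou_mean + (drive[k] - ou_mean) * ou_dec + ou_noise * norm_rand();

    // delayed coupling sums (off-diagonal, scaled by S) at t and t+dt
    for (int k = 0; k < n; ++k) {
      double acc = 0.0, acc2 = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == k) continue;
        const double w = weights(j, k);
        if (w == 0.0) continue;
        const int d = delay_steps(j, k);
        int s1 = step - d;          // for time t
        int s2 = step + 1 - d;      // for time t+dt (d>=1 => known history)
        if (s1 < 0) s1 = 0;
        if (s2 < 0) s2 = 0;
        if (s2 > step) s2 = step;   // d==0 handled via self term, not here
        acc += w * hist[(size_t)j * L + (s1 % L)];
        acc2 += w * hist[(size_t)j * L + (s2 % L)];
      }
      coup[k] = S * acc;
      coup_next[k] = S * acc2;
    }

    const bool stim_on_t =
        stim_target >= 0 && t >= stim_onset && t < stim_onset + stim_dur;
    const bool stim_on_t2 = stim_target >= 0 && (t + dt) >= stim_onset &&
                            (t + dt) < stim_onset + stim_dur;

    // Heun predictor
    for (int k = 0; k < n; ++k) {
      double in_e = drive[k] + fe[k] + coup[k] + nu_aff;
      double in_stim = in_e + ((stim_on_t && k == stim_target) ? stim_amp : 0);
      const double Fe = tf_rate(in_stim < 0 ? 0 : in_stim, fi[k], W[k], pe);
      const double Fi = tf_rate(in_e < 0 ? 0 : in_e, fi[k], 0.0, pi);
      adexbrain::VoltageMoments m =
          adexbrain::voltage_moments(fe[k], fi[k], W[k], pe);
      const double dfe = (Fe - fe[k]) / T;
      const double dfi = (Fi - fi[k]) / T;
      const double dW = -W[k] / uw + b * fe[k] + a * (m.muV - EL);
      fe_pred[k] = fe[k] + dt * dfe;
      fi_pred[k] = fi[k] + dt * dfi;
      W_pred[k] = W[k] + dt * dW;
      if (fe_pred[k] < 0) fe_pred[k] = 0;
      if (fi_pred[k] < 0) fi_pred[k] = 0;
      k1fe[k] = dfe;
      k1fi[k] = dfi;
      k1W[k] = dW;
    }

    // Heun corrector: delayed terms at t+dt, self term from predictor
    for (int k = 0; k < n; ++k) {
      double in_e = drive_next[k] + fe_pred[k] + coup_next[k] + nu_aff;
      double in_stim =
          in_e + ((stim_on_t2 && k == stim_target) ? stim_amp : 0);
      const double Fe =
          tf_rate(in_stim < 0 ? 0 : in_stim, fi_pred[k], W_pred[k], pe);
      const double Fi = tf_rate(in_e < 0 ? 0 : in_e, fi_pred[k], 0.0, pi);
      adexbrain::VoltageMoments m =
          adexbrain::voltage_moments(fe_pred[k], fi_pred[k], W_pred[k], pe);
      const double dfe = (Fe - fe_pred[k]) / T;
      const double dfi = (Fi - fi_pred[k]) / T;
      const double dW = -W_pred[k] / uw + b * fe_pred[k] + a * (m.muV - EL);
      fe[k] += 0.5 * dt * (k1fe[k] + dfe);
      fi[k] += 0.5 * dt * (k1fi[k] + dfi);
      W[k] += 0.5 * dt * (k1W[k] + dW);
      if (fe[k] < 0) fe[k] = 0;
      if (fi[k] < 0) fi[k] = 0;
      if (!std::isfinite(fe[k]))
        stop("brain-network state diverged at t=%f ms, region %d", t, k);
    }
    for (int k = 0; k < n; ++k) drive[k] = drive_next[k];
    if (step % 10000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["time"] = t_out, _["nu_e"] = fe_out,
                      _["nu_i"] = fi_out, _["W"] = W_out);
}
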