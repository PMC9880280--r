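#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward-Euler integration of a conductance-based AdEx network, dt in ms.
// Synaptic conductances decay exponentially between spikes (exact update)
// and jump by Q on presynaptic spikes; the exponential spike-initiation
// term is guard-clamped at +10 in its argument (spike detection at v_peak
// makes the clamp consequence-free). Refractory neurons are clamped at
// v_reset while w keeps evolving.
//
// Adjacency is CSR over presynaptic neurons: targets of neuron i are
// adj_idx[adj_ptr[i] .. adj_ptr[i+1]-1] (0-based).
//
// External drive: network-total Poisson event stream at rate
// N * drive_rate_khz, each event delivered through a Q_e synapse of a
// uniformly chosen neuron (equivalent to independent per-neuron streams).

// [[Rcpp::export]]
List sim_adex_network_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                          IntegerVector is_inh, List params, double duration,
                          double dt, double drive_rate_khz, NumericVector v0,
                          NumericVector w0, IntegerVector monitor,
                          int record_every) {
  const int N = is_inh.size();
  const double Cm = params["c_m"], gL = params["g_L"];
  const double EL_e = params["E_L_e"], EL_i = params["E_L_i"];
  const double De = params["Delta_e"], Di = params["Delta_i"];
  const double vthr = params["v_thr"];
  const double vpk_e = params["v_peak_e"], vpk_i = params["v_peak_i"];
  const double vreset = params["v_reset"], Trefr = params["T_refr"];
  const double a_e = params["a"], b_e = params["b"], tauw = params["u_w"];
  const double Qe = params["Q_e"], Qi = params["Q_i"];
  const double Ee = params["E_e"], Ei = params["E_i"];
  const double taue = params["u_e"], taui = params["u_i"];

  const int nsteps = (int)std::lround(duration / dt);
  const int refr_steps = (int)std::lround(Trefr / dt);
  const double dec_e = std::exp(-dt / taue), dec_i = std::exp(-dt / taui);
  const double lam_ext = N * drive_rate_khz * dt;

  std::vector<double> v(v0.begin(), v0.end()), w(w0.begin(), w0.end());
  std::vector<double> Ge(N, 0.0), Gi(N, 0.0);
  std::vector<int> refr(N, 0);
  std::vector<double> EL(N), Delta(N), vpk(N), a_(N), b_(N);
  for (int i = 0; i < N; ++i) {
    if (is_inh[i]) {
      EL[i] = EL_i; Delta[i] = Di; vpk[i] = vpk_i; a_[i] = 0.0; b_[i] = 0.0;
    } else {
      EL[i] = EL_e; Delta[i] = De; vpk[i] = vpk_e; a_[i] = a_e; b_[i] = b_e;
    }
  }

  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  std::vector<int> spiked;
  spiked.reserve(256);

  const int nmon = monitor.size();
  const int nrec = (nmon > 0) ? ((nsteps - 1) / record_every + 1) : 0;
  NumericMatrix tr_v(nrec, nmon), tr_w(nrec, nmon), tr_ge(nrec, nmon),
      tr_gi(nrec, nmon);
  NumericVector tr_t(nrec);
  int irec = 0;

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    if (nmon > 0 && step % record_every == 0 && irec < nrec) {
      for (int m = 0; m < nmon; ++m) {
        const int id = monitor[m];
        tr_v(irec, m) = v[id]; tr_w(irec, m) = w[id];
        tr_ge(irec, m) = Ge[id]; tr_gi(irec, m) = Gi[id];
      }
      tr_t[irec++] = t;
    }
    const int K = (int)R::rpois(lam_ext);
    for (int k = 0; k < K; ++k) {
      int n = (int)(unif_rand() * N);
      if (n >= N) n = N - 1;
      Ge[n] += Qe;
    }
    spiked.clear();
    for (int i = 0; i < N; ++i) {
      const double ge = Ge[i], gi = Gi[i];
      if (refr[i] > 0) {
        --refr[i];
        v[i] = vreset;
        w[i] += dt * (-w[i] + a_[i] * (vreset - EL[i])) / tauw;
      } else {
        const double vv = v[i];
        double darg = (vv - vthr) / Delta[i];
        if (darg > 10.0) darg = 10.0;
        const double Isyn = ge * (Ee - vv) + gi * (Ei - vv);
        const double dv =
            (gL * (EL[i] - vv) + gL * Delta[i] * std::exp(darg) - w[i] + Isyn) /
            Cm;
        v[i] = vv + dt * dv;
        w[i] += dt * (-w[i] + a_[i] * (vv - EL[i])) / tauw;
        if (v[i] > vpk[i]) {
          sp_neuron.push_back(i);
          sp_time.push_back(t + dt);
          v[i] = vreset;
          w[i] += b_[i];
          refr[i] = refr_steps;
          spiked.push_back(i);
        }
      }
      if (!std::isfinite(v[i]))
        stop("NaN/Inf membrane potential at t=%f ms, neuron %d", t, i);
      Ge[i] = ge * dec_e;
      Gi[i] = gi * dec_i;
    }
    for (size_t s = 0; s < spiked.size(); ++s) {
      const int i = spiked[s];
      const double q = is_inh[i] ? Qi : Qe;
      for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) {
        if (is_inh[i]) Gi[adj_idx[e]] += q; else Ge[adj_idx[e]] += q;
      }
    }
  }

  List out = List::create(
      _["neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
      _["time"] = NumericVector(sp_time.begin(), sp_time.end()));
  if (nmon > 0) {
    out["trace_time"] = tr_t;
    out["trace_v"] = tr_v;
    out["trace_w"] = tr_w;
    out["trace_ge"] = tr_ge;
    out["trace_gi"] = tr_gi;
  }
  return out;
}

// Stationary output rate of a single AdEx neuron bombarded by K_e/K_i
// independent Poisson trains at per-synapse rates fe/fi (kHz), with the
// adaptation current frozen at W (pA). Used to calibrate the transfer
// function. Returns rates in kHz, averaged over n_rep repetitions.

// [[Rcpp::export]]
NumericVector sim_single_neuron_rates_cpp(List params, bool inhibitory,
                                          NumericVector fe, NumericVector fi,
                                          NumericVector W, double Ke,
                                          double Ki, double duration,
                                          double transient, double dt,
                                          int n_rep) {
  const double Cm = params["c_m"], gL = params["g_L"];
  const double EL = inhibitory ? (double)params["E_L_i"]
                               : (double)params["E_L_e"];
  const double Delta = inhibitory ? (double)params["Delta_i"]
                                  : (double)params["Delta_e"];
  const double vpk = inhibitory ? (double)params["v_peak_i"]
                                : (double)params["v_peak_e"];
  const double vthr = params["v_thr"], vreset = params["v_reset"];
  const double Trefr = params["T_refr"];
  const double Qe = params["Q_e"], Qi = params["Q_i"];
  const double Ee = params["E_e"], Ei = params["E_i"];
  const double taue = params["u_e"], taui = params["u_i"];

  const int npts = fe.size();
  const int nsteps = (int)std::lround(duration / dt);
  const int tr_steps = (int)std::lround(transient / dt);
  const int refr_steps = (int)std::lround(Trefr / dt);
  const double dec_e = std::exp(-dt / taue), dec_i = std::exp(-dt / taui);
  NumericVector out(npts);

  for (int pt = 0; pt < npts; ++pt) {
    const double lam_e = Ke * fe[pt] * dt, lam_i = Ki * fi[pt] * dt;
    const double w = W[pt];
    long total_spikes = 0;
    for (int rep = 0; rep < n_rep; ++rep) {
      double v = EL, ge = 0.0, gi = 0.0;
      int refr = 0;
      for (int step = 0; step < nsteps; ++step) {
        if (lam_e > 0) ge += Qe * R::rpois(lam_e);
        if (lam_i > 0) gi += Qi * R::rpois(lam_i);
        if (refr > 0) {
          --refr;
          v = vreset;
        } else {
          double darg = (v - vthr) / Delta;
          if (darg > 10.0) darg = 10.0;
          const double dv = (gL * (EL - v) + gL * Delta * std::exp(darg) - w +
                             ge * (Ee - v) + gi * (Ei - v)) /
                            Cm;
          v += dt * dv;
          if (v > vpk) {
            if (step >= tr_steps) ++total_spikes;
            v = vreset;
            refr = refr_steps;
          }
        }
        ge *= dec_e;
        gi *= dec_i;
      }
    }
    out[pt] = (double)total_spikes / (n_rep * (duration - transient));
    Rcpp::checkUserInterrupt();
  }
  return out;  // kHz
}
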