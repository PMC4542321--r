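#include <Rcpp.h>
#include <vector>
#include <cmath>

#if defined(__GNUC__) || defined(__clang__)
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif
using namespace Rcpp;

// Leaky integrate-and-fire network with exponential synapses.
//
// Forward-Euler integration of tau dV/dt = -V + R_m I, threshold/reset, with
// recurrent currents carried by two per-neuron aggregated synaptic traces
// (one per presynaptic population, since all synapses from a population share
// a time constant). Each trace decays as exp(-dt/tau_syn) and jumps by
// g * w / tau_syn when a presynaptic neuron spikes; this is mathematically
// identical to summing exponential kernels over all past spikes, at
// O(N + spikes * out-degree) cost per step.
//
// Within-step order: (1) decay traces, (2) currents from previous spikes,
// (3) Euler update, (4) threshold/reset, (5) STDP updates from this step's
// spikes (traces not yet bumped, so exactly simultaneous pairs contribute
// nothing), (6) bump plasticity traces, (7) propagate spikes into synaptic
// traces (one-step transmission latency).
//
// STDP (multiplicative pair rule, all-to-all pairing via exponential traces)
// acts only on edges with excitatory presynaptic neurons; inhibitory weights
// stay at 1.
//
// Indexing: global neuron ids 0..n-1, excitatory first. fwd_* is a CSR over
// presynaptic id. Initial V is uniform on [v_reset, v_t) from R's RNG unless
// v_init is supplied.
// [[Rcpp::export]]
List lif_run_cpp(int n_e, int n_i,
                 IntegerVector fwd_ptr, IntegerVector fwd_post,
                 NumericVector fwd_w_in,
                 NumericVector i_ff, NumericVector i_back,
                 double tau, double r_m, double v_t, double v_reset,
                 double tau_syn_e, double tau_syn_i,
                 double g_ee, double g_ei, double g_ie, double g_ii,
                 double dt, int n_steps,
                 bool stdp, double a_plus, double a_minus,
                 double tau_plus, double tau_minus,
                 double w_max, int plastic_steps,
                 int probe, int probe_every,
                 bool avg_input, int avg_from_step,
                 Nullable<NumericVector> v_init) {
  const int n = n_e + n_i;
  if (i_ff.size() != n || i_back.size() != n)
    stop("current vectors must have length n_e + n_i");
  NumericVector w = clone(fwd_w_in);
  std::vector<double> v(n), ce(n, 0.0), ci(n, 0.0);
  if (v_init.isNotNull()) {
    NumericVector vi(v_init);
    if (vi.size() != n) stop("v_init must have length n_e + n_i");
    for (int i = 0; i < n; ++i) v[i] = vi[i];
  } else {
    for (int i = 0; i < n; ++i) v[i] = v_reset + unif_rand() * (v_t - v_reset);
  }
  const double de = std::exp(-dt / tau_syn_e), di = std::exp(-dt / tau_syn_i);
  const double dxp = std::exp(-dt / tau_plus), dyp = std::exp(-dt / tau_minus);
  const double euler = dt / tau;

  // backward adjacency over excitatory-presynaptic edges (for potentiation)
  std::vector<int> bwd_ptr, bwd_edge, bwd_pre;
  if (stdp) {
    std::vector<int> cnt(n, 0);
    for (int j = 0; j < n_e; ++j)
      for (int e = fwd_ptr[j]; e < fwd_ptr[j + 1]; ++e) cnt[fwd_post[e]]++;
    bwd_ptr.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) bwd_ptr[i + 1] = bwd_ptr[i] + cnt[i];
    bwd_edge.assign(bwd_ptr[n], 0);
    bwd_pre.assign(bwd_ptr[n], 0);
    std::vector<int> fill(bwd_ptr.begin(), bwd_ptr.end() - 1);
    for (int j = 0; j < n_e; ++j)
      for (int e = fwd_ptr[j]; e < fwd_ptr[j + 1]; ++e) {
        int i = fwd_post[e];
        bwd_edge[fill[i]] = e;
        bwd_pre[fill[i]] = j;
        ++fill[i];
      }
  }

  std::vector<double> xpre(stdp ? n_e : 0, 0.0), ypost(stdp ? n : 0, 0.0);
  std::vector<int> sp;
  sp.reserve(512);
  std::vector<int> sp_id;
  std::vector<double> sp_t;
  std::vector<double> pr_t, pr_exc, pr_inh;
  std::vector<double> sum_exc(avg_input ? n : 0, 0.0),
      sum_inh(avg_input ? n : 0, 0.0);
  long avg_count = 0;

  // hoisted constants and raw buffers for the hot per-neuron loop:
  // V <- V (1 - dt/tau) + (dt/tau) R_m (I_ff + I_back) + (dt/tau) R_m I_rec
  std::vector<double> ext(n), drive(n);
  for (int i = 0; i < n; ++i) {
    ext[i] = i_ff[i] + i_back[i];
    drive[i] = euler * r_m * ext[i];
  }
  const double keep = 1.0 - euler, ar = euler * r_m;
  double* RESTRICT pv = v.data();
  double* RESTRICT pce = ce.data();
  double* RESTRICT pci = ci.data();
  const double* RESTRICT pdrive = drive.data();
  const double* RESTRICT pext = ext.data();
  double* RESTRICT pw = REAL(w);

  for (int s = 0; s < n_steps; ++s) {
    const bool plastic = stdp && s < plastic_steps;
    if (plastic) {
      for (int j = 0; j < n_e; ++j) xpre[j] *= dxp;
      for (int i = 0; i < n; ++i) ypost[i] *= dyp;
    }
    sp.clear();
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      double c_e = pce[i] * de, c_i = pci[i] * di;
      pce[i] = c_e;
      pci[i] = c_i;
      double vi = pv[i] * keep + pdrive[i] + ar * (c_e + c_i);
      if (vi >= v_t) {
        if (!std::isfinite(vi)) bad = true;
        sp.push_back(i);
        vi = v_reset;
      }
      pv[i] = vi;
    }
    if (bad) stop("non-finite membrane potential at t = %.3f ms", s * dt);
    if ((s & 2047) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(pv[i]))
          stop("non-finite membrane potential at t = %.3f ms, neuron %d",
               s * dt, i + 1);
    }
    if (probe >= 0 && s % probe_every == 0) {
      pr_t.push_back(s * dt);
      pr_exc.push_back(pext[probe] + pce[probe]);
      pr_inh.push_back(pci[probe]);
    }
    if (avg_input && s >= avg_from_step) {
      for (int i = 0; i < n; ++i) {
        sum_exc[i] += pext[i] + pce[i];
        sum_inh[i] += pci[i];
      }
      ++avg_count;
    }
    if (plastic && !sp.empty()) {
      for (size_t q = 0; q < sp.size(); ++q) {  // post-triggered potentiation
        int i = sp[q];
        for (int b = bwd_ptr[i]; b < bwd_ptr[i + 1]; ++b) {
          double x = xpre[bwd_pre[b]];
          if (x > 0) {
            int e = bwd_edge[b];
            double we = pw[e] + a_plus * x * (w_max - pw[e]);
            pw[e] = we < 0 ? 0 : (we > w_max ? w_max : we);
          }
        }
      }
      for (size_t q = 0; q < sp.size(); ++q) {  // pre-triggered depression
        int j = sp[q];
        if (j < n_e) {
          for (int e = fwd_ptr[j]; e < fwd_ptr[j + 1]; ++e) {
            double y = ypost[fwd_post[e]];
            if (y > 0) {
              double we = pw[e] + a_minus * y * pw[e];
              pw[e] = we < 0 ? 0 : (we > w_max ? w_max : we);
            }
          }
        }
      }
      for (size_t q = 0; q < sp.size(); ++q) {
        if (sp[q] < n_e) xpre[sp[q]] += 1.0;
        ypost[sp[q]] += 1.0;
      }
    }
    for (size_t q = 0; q < sp.size(); ++q) {
      int j = sp[q];
      const bool pre_e = j < n_e;
      double* tr = pre_e ? pce : pci;
      const double inv_tau = pre_e ? 1.0 / tau_syn_e : 1.0 / tau_syn_i;
      for (int e = fwd_ptr[j]; e < fwd_ptr[j + 1]; ++e) {
        int tgt = fwd_post[e];
        double g = pre_e ? (tgt < n_e ? g_ee : g_ie)
                         : (tgt < n_e ? g_ei : g_ii);
        tr[tgt] += g * pw[e] * inv_tau;
      }
      sp_id.push_back(j + 1);
      sp_t.push_back((s + 1) * dt);
    }
  }

  List out = List::create(
      _["spike_id"] = wrap(sp_id), _["spike_t"] = wrap(sp_t),
      _["w"] = w, _["v"] = wrap(v));
  if (probe >= 0) {
    out["probe_t"] = wrap(pr_t);
    out["probe_exc"] = wrap(pr_exc);
    out["probe_inh"] = wrap(pr_inh);
  }
  if (avg_input && avg_count > 0) {
    NumericVector ae(n), ai(n);
    for (int i = 0; i < n; ++i) {
      ae[i] = sum_exc[i] / avg_count;
      ai[i] = sum_inh[i] / avg_count;
    }
    out["avg_exc"] = ae;
    out["avg_inh"] = ai;
  }
  return out;
}
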