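#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Adaptive exponential integrate-and-fire network with bi-exponential
// conductance synapses, forward Euler at dt_ms, refractory clamping, and a
// synaptic-current LFP proxy summed over a sampled subset of neurons.
//
// params: one row per neuron type, columns
//   Cm(pF) gL(nS) EL(mV) theta(mV) DeltaT(mV) Vpeak(mV) Vreset(mV)
//   tref(ms) tauw(ms) a(nS) b(pA)
// channels: one row per synaptic channel, columns tau_rise(ms) tau_decay(ms)
//   e_rev(mV). Conductances are normalized so one spike of weight w peaks
//   at w (nS).
// edges: src,dst 0-based; per-edge weight (nS), channel, delay (steps).
// ext_*: pre-scheduled external deliveries (step, target, weight, channel).
// [[Rcpp::export]]
List aelif_net_cpp(int n_neurons, IntegerVector type, NumericMatrix params,
                   NumericMatrix channels,
                   IntegerVector edge_src, IntegerVector edge_dst,
                   NumericVector edge_w, IntegerVector edge_ch,
                   IntegerVector edge_delay_steps,
                   IntegerVector ext_step, IntegerVector ext_target,
                   NumericVector ext_w, IntegerVector ext_ch,
                   double duration_ms, double dt_ms,
                   IntegerVector lfp_ids, int lfp_every_steps,
                   double lfp_gain, NumericVector v0) {
  int n_steps = (int)std::round(duration_ms / dt_ms);
  int n_ch = channels.nrow();
  int ne = edge_src.size();

  // channel constants
  std::vector<double> dec_r(n_ch), dec_d(n_ch), norm(n_ch), erev(n_ch);
  for (int c = 0; c < n_ch; ++c) {
    double tr = channels(c, 0), td = channels(c, 1);
    dec_r[c] = std::exp(-dt_ms / tr);
    dec_d[c] = std::exp(-dt_ms / td);
    double tpk = tr * td / (td - tr) * std::log(td / tr);
    norm[c] = 1.0 / (std::exp(-tpk / td) - std::exp(-tpk / tr));
    erev[c] = channels(c, 2);
  }

  // per-neuron per-channel conductance states
  std::vector<double> g_d((size_t)n_neurons * n_ch, 0.0);
  std::vector<double> g_r((size_t)n_neurons * n_ch, 0.0);

  // CSR out-edges
  std::vector<int> off(n_neurons + 1, 0);
  for (int e = 0; e < ne; ++e) off[edge_src[e] + 1]++;
  for (int i = 0; i < n_neurons; ++i) off[i + 1] += off[i];
  std::vector<int> eidx(ne);
  { std::vector<int> cur(off.begin(), off.end() - 1);
    for (int e = 0; e < ne; ++e) eidx[cur[edge_src[e]]++] = e; }

  // delay ring buffer of spiking neuron ids
  int max_delay = 1;
  for (int e = 0; e < ne; ++e)
    if (edge_delay_steps[e] > max_delay) max_delay = edge_delay_steps[e];
  std::vector<std::vector<int>> ring(max_delay + 1);

  std::vector<double> V(n_neurons), w_adapt(n_neurons, 0.0);
  std::vector<int> ref_left(n_neurons, 0);
  for (int i = 0; i < n_neurons; ++i) V[i] = v0[i];

  std::vector<double> spk_t; std::vector<int> spk_id;
  int n_lfp_samp = n_steps / lfp_every_steps + 1;
  NumericVector lfp(n_lfp_samp); int lfp_n = 0;
  std::vector<char> in_lfp(n_neurons, 0);
  for (int k = 0; k < lfp_ids.size(); ++k) in_lfp[lfp_ids[k]] = 1;

  int ext_ptr = 0, n_ext = ext_step.size();

  for (int s = 0; s < n_steps; ++s) {
    // deliver delayed internal spikes scheduled for this step
    std::vector<int>& due = ring[s % (max_delay + 1)];
    for (int src : due) {
      for (int k = off[src]; k < off[src + 1]; ++k) {
        int e = eidx[k];
        int tgt = edge_dst[e], ch = edge_ch[e];
        double inc = edge_w[e] * norm[ch];
        g_d[(size_t)tgt * n_ch + ch] += inc;
        g_r[(size_t)tgt * n_ch + ch] += inc;
      }
    }
    due.clear();
    // external deliveries
    while (ext_ptr < n_ext && ext_step[ext_ptr] == s) {
      int tgt = ext_target[ext_ptr], ch = ext_ch[ext_ptr];
      double inc = ext_w[ext_ptr] * norm[ch];
      g_d[(size_t)tgt * n_ch + ch] += inc;
      g_r[(size_t)tgt * n_ch + ch] += inc;
      ++ext_ptr;
    }
    double lfp_acc = 0.0;
    bool take_lfp = (s % lfp_every_steps) == 0;
    for (int i = 0; i < n_neurons; ++i) {
      int ty = type[i];
      double Cm = params(ty, 0), gL = params(ty, 1), EL = params(ty, 2),
             th = params(ty, 3), DT = params(ty, 4), Vpk = params(ty, 5),
             Vrs = params(ty, 6), tref = params(ty, 7), tauw = params(ty, 8),
             aa = params(ty, 9), bb = params(ty, 10);
      // synaptic current (pA): g (nS) * (V - E) (mV)
      double Is = 0.0;
      size_t base = (size_t)i * n_ch;
      for (int c = 0; c < n_ch; ++c) {
        double g = g_d[base + c] - g_r[base + c];
        if (g != 0.0) Is += g * (V[i] - erev[c]);
      }
      if (take_lfp && in_lfp[i]) lfp_acc += Is;
      if (ref_left[i] > 0) {
        ref_left[i]--;
        V[i] = Vrs;
        w_adapt[i] += dt_ms * (aa * (V[i] - EL) - w_adapt[i]) / tauw;
      } else {
        double expo = (V[i] - th) / DT;
        if (expo > 20.0) expo = 20.0;  // guard overflow; spike fires below
        double dV = -(gL * (V[i] - EL) - gL * DT * std::exp(expo) + Is +
                      w_adapt[i]) / Cm;
        V[i] += dt_ms * dV;
        w_adapt[i] += dt_ms * (aa * (V[i] - EL) - w_adapt[i]) / tauw;
        if (V[i] >= Vpk) {
          V[i] = Vrs;
          w_adapt[i] += bb;
          ref_left[i] = (int)std::round(tref / dt_ms);
          spk_t.push_back((s + 1) * dt_ms);
          spk_id.push_back(i + 1);
          // schedule synaptic delivery (per-edge delay; all edges of a
          // neuron share one delay in this model, use the first edge's)
          int d = 1;
          if (off[i] < off[i + 1]) d = edge_delay_steps[eidx[off[i]]];
          ring[(s + d) % (max_delay + 1)].push_back(i);
        }
      }
    }
    if (take_lfp) { lfp[lfp_n++] = lfp_gain * lfp_acc * 1e-12; }
    for (size_t k = 0; k < g_d.size(); ++k) {
      int c = k % n_ch;
      g_d[k] *= dec_d[c];
      g_r[k] *= dec_r[c];
    }
  }
  return List::create(_["spike_t_ms"] = wrap(spk_t),
                      _["spike_id"] = wrap(spk_id),
                      _["lfp"] = lfp[Range(0, std::max(0, lfp_n - 1))],
                      _["lfp_dt_ms"] = dt_ms * lfp_every_steps);
}
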