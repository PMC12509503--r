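#include <Rcpp.h>
using namespace Rcpp;

// Inhomogeneous-Poisson place-cell spikes during clamped exploration.
// Rate: lambda_max * (1/2 + 1/2 cos(2 pi f_theta t + (pi/sigma) sign(x_i)
// (x(t) - x_i))) * exp(-(x(t)-x_i)^2 / (2 sigma^2))  -- place tuning with
// theta phase precession. Cells are visited only when |x - x_i| < 4 sigma.
// Uses R's RNG so set.seed() on the R side makes draws reproducible.
// [[Rcpp::export]]
List place_spikes_cpp(NumericVector x, double dt_s,
                      NumericVector centers, double lambda_max,
                      double sigma, double f_theta) {
  int nt = x.size(), nc = centers.size();
  // sort cells by center for windowed lookup
  std::vector<int> ord(nc);
  for (int i = 0; i < nc; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return centers[a] < centers[b]; });
  std::vector<double> cs(nc);
  for (int i = 0; i < nc; ++i) cs[i] = centers[ord[i]];
  std::vector<double> st, sid;
  double win = 4.0 * sigma;
  for (int t = 0; t < nt; ++t) {
    double xt = x[t], tt = t * dt_s;
    int lo = std::lower_bound(cs.begin(), cs.end(), xt - win) - cs.begin();
    int hi = std::upper_bound(cs.begin(), cs.end(), xt + win) - cs.begin();
    for (int k = lo; k < hi; ++k) {
      double xi = cs[k];
      double d = xt - xi;
      double phase = 2.0 * M_PI * f_theta * tt +
        M_PI / sigma * ((xi >= 0) ? 1.0 : -1.0) * d;
      double lam = lambda_max * (0.5 + 0.5 * std::cos(phase)) *
        std::exp(-d * d / (2.0 * sigma * sigma));
      if (lam * dt_s > 0 && unif_rand() < lam * dt_s) {
        st.push_back(tt);
        sid.push_back(ord[k] + 1);  // 1-based neuron index
      }
    }
  }
  return List::create(_["t_s"] = wrap(st), _["id"] = wrap(sid));
}

struct Edge { int dst; };

// All-pairs trace-based STDP over a merged, time-sorted spike stream.
// Each spike acts first as post (potentiation from pre traces, dt > 0
// branch) and as pre (depression/facilitation from post traces, dt <= 0
// branch with asymmetry alpha), then increments its own traces. Weights are
// normalized (w in [0,1]) and clipped after every update.
// [[Rcpp::export]]
NumericVector stdp_train_cpp(NumericVector spk_t, IntegerVector spk_id,
                             IntegerVector spk_is_pre, IntegerVector spk_is_post,
                             int n_pre, int n_post,
                             IntegerVector edge_src, IntegerVector edge_dst,
                             NumericVector w0,
                             double lambda, double alpha,
                             double tau_plus_ms, double tau_minus_ms) {
  int ne = edge_src.size(), ns = spk_t.size();
  NumericVector w = clone(w0);
  // CSR adjacency: out-edges by src, in-edges by dst (0-based ids)
  std::vector<std::vector<int>> out_e(n_pre), in_e(n_post);
  for (int e = 0; e < ne; ++e) {
    out_e[edge_src[e]].push_back(e);
    in_e[edge_dst[e]].push_back(e);
  }
  std::vector<double> pre_tr(n_pre, 0.0), pre_last(n_pre, -1e18);
  std::vector<double> post_tr(n_post, 0.0), post_last(n_post, -1e18);
  double tp = tau_plus_ms / 1000.0, tm = tau_minus_ms / 1000.0;
  for (int s = 0; s < ns; ++s) {
    double t = spk_t[s];
    int id = spk_id[s];  // 0-based within its population role
    if (spk_is_post[s]) {
      // potentiation: pair with all earlier pre spikes (dt > 0)
      for (int e : in_e[id]) {
        int src = edge_src[e];
        double tr = pre_tr[src] * std::exp(-(t - pre_last[src]) / tp);
        double nw = w[e] + lambda * tr;
        w[e] = std::min(1.0, std::max(0.0, nw));
      }
    }
    if (spk_is_pre[s]) {
      // dt <= 0 branch: -lambda * alpha per earlier post spike
      for (int e : out_e[id]) {
        int dst = edge_dst[e];
        double tr = post_tr[dst] * std::exp(-(t - post_last[dst]) / tm);
        double nw = w[e] - lambda * alpha * tr;
        w[e] = std::min(1.0, std::max(0.0, nw));
      }
    }
    if (spk_is_pre[s]) {
      pre_tr[id] = pre_tr[id] * std::exp(-(t - pre_last[id]) / tp) + 1.0;
      pre_last[id] = t;
    }
    if (spk_is_post[s]) {
      post_tr[id] = post_tr[id] * std::exp(-(t - post_last[id]) / tm) + 1.0;
      post_last[id] = t;
    }
  }
  return w;
}
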