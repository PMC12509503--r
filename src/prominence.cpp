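#include <Rcpp.h>
using namespace Rcpp;

// Topographic prominence of local maxima, scipy-compatible: for each peak,
// scan left/right until a strictly higher sample (or the signal edge); the
// prominence is peak height minus the higher of the two interval minima.
// [[Rcpp::export]]
List peak_prominences_cpp(NumericVector x) {
  int n = x.size();
  std::vector<int> peaks;
  int i = 1;
  while (i < n - 1) {
    if (x[i - 1] < x[i]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[i]) ++j;   // plateau
      if (j < n - 1 && x[j + 1] < x[i]) {
        peaks.push_back((i + j) / 2);
        i = j + 1;
        continue;
      }
      i = j + 1;
    } else {
      ++i;
    }
  }
  int np = peaks.size();
  NumericVector prom(np);
  IntegerVector idx(np);
  for (int p = 0; p < np; ++p) {
    int ip = peaks[p];
    double h = x[ip];
    double lmin = h, rmin = h;
    for (int k = ip - 1; k >= 0; --k) {
      if (x[k] > h) break;
      if (x[k] < lmin) lmin = x[k];
    }
    for (int k = ip + 1; k < n; ++k) {
      if (x[k] > h) break;
      if (x[k] < rmin) rmin = x[k];
    }
    prom[p] = h - std::max(lmin, rmin);
    idx[p] = ip + 1;  // 1-based for R
  }
  return List::create(_["index"] = idx, _["prominence"] = prom);
}
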