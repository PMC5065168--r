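#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact penalized least-squares changepoint detection.
//
// Minimizes  sum_k RSS(segment_k) + penalty * (number of segments)
// over all partitions of x into contiguous segments of length >= min_len.
// Returns the 1-based end index of each segment. O(n^2) time; the search
// is exhaustive, so the result is the global optimum (ties broken toward
// the earlier previous-changepoint candidate).
// [[Rcpp::export(name = ".dp_changepoints")]]
IntegerVector dp_changepoints(NumericVector x, double penalty, int min_len) {
  int n = x.size();
  if (n < min_len) stop("fewer observations than `min_len`");
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> last(n + 1, 0);
  F[0] = -penalty;
  for (int t = min_len; t <= n; ++t) {
    double best = R_PosInf;
    int arg = 0;
    for (int s = 0; s + min_len <= t; ++s) {
      if (s != 0 && s < min_len) continue;          // segment before s too short
      if (!R_FINITE(F[s])) continue;
      double len = (double)(t - s);
      double sum = cs[t] - cs[s];
      double cost = cs2[t] - cs2[s] - sum * sum / len;
      double val = F[s] + cost + penalty;
      if (val < best) { best = val; arg = s; }
    }
    F[t] = best;
    last[t] = arg;
  }
  std::vector<int> ends;
  for (int t = n; t > 0; t = last[t]) ends.push_back(t);
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
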