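#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <utility>
#include <vector>

using namespace Rcpp;

// Greedy 1:1 nearest-neighbour caliper matching without replacement on the
// logit propensity scale.  Treated units are processed in decreasing order
// of logit_ps (ties by row index); each takes the unused control with the
// smallest absolute difference, skipped when none lies within the caliper.
// Equidistant controls resolve to the smaller logit value, then the smaller
// row index.  Controls live in an ordered set keyed by (value, index), so
// the whole pass is O((T + C) log C).
// [[Rcpp::export]]
List greedy_match_cpp(NumericVector logit_ps, IntegerVector z, double caliper) {
  const int n = logit_ps.size();
  std::vector<int> treated;
  std::set<std::pair<double, int> > controls;
  for (int i = 0; i < n; ++i) {
    if (z[i] == 1) {
      treated.push_back(i);
    } else {
      controls.insert(std::make_pair(logit_ps[i], i));
    }
  }
  std::stable_sort(treated.begin(), treated.end(),
                   [&](int a, int b) {
                     if (logit_ps[a] != logit_ps[b])
                       return logit_ps[a] > logit_ps[b];
                     return a < b;
                   });

  std::vector<int> t_out, c_out;
  t_out.reserve(treated.size());
  c_out.reserve(treated.size());
  for (size_t ti = 0; ti < treated.size(); ++ti) {
    if (controls.empty()) break;
    const int t = treated[ti];
    const double v = logit_ps[t];
    // first control with value >= v (smallest index among exact ties)
    std::set<std::pair<double, int> >::iterator hi =
        controls.lower_bound(std::make_pair(v, -1));
    bool have = false;
    std::set<std::pair<double, int> >::iterator best;
    double bestd = 0.0;
    if (hi != controls.begin()) {
      std::set<std::pair<double, int> >::iterator lo = hi;
      --lo;
      // among equal-valued controls below v, take the smallest row index
      best = controls.lower_bound(std::make_pair(lo->first, -1));
      bestd = v - lo->first;
      have = true;
    }
    if (hi != controls.end()) {
      const double d = hi->first - v;
      // strict <: on an exact distance tie keep the lower logit (the
      // candidate below v); a zero-distance hit always wins
      if (!have || d < bestd) {
        best = hi;
        bestd = d;
        have = true;
      }
    }
    if (have && bestd <= caliper) {
      t_out.push_back(t + 1);
      c_out.push_back(best->second + 1);
      controls.erase(best);
    }
  }
  return List::create(_["treated"] = wrap(t_out), _["control"] = wrap(c_out));
}
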