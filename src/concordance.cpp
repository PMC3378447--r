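#include <Rcpp.h>
using namespace Rcpp;

// Harrell's C with the usable-pair rule.
// Anchored at the earlier uncensored subject i of each pair:
//   - j uncensored: usable iff X_j > X_i (equal event times unusable);
//   - j censored:   usable iff X_j >= X_i (censored at or after i's event).
// A pair is concordant when the higher risk score belongs to the earlier
// event; score ties count 1/2.  Also returns per-subject concordance and
// usable-pair totals (each pair credited to both members) for the
// U-statistic variance.

// [[Rcpp::export]]
List concordance_cpp(NumericVector time, IntegerVector status,
                     NumericVector score) {
  const int n = time.size();
  double conc = 0.0, usable = 0.0, tied = 0.0;
  NumericVector Pi(n), Qi(n);
  for (int i = 0; i < n; i++) {
    if (status[i] != 1) continue;
    const double ti = time[i], si = score[i];
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      bool use;
      if (status[j] == 1) use = time[j] > ti;
      else use = time[j] >= ti;
      if (!use) continue;
      double c;
      if (si > score[j]) c = 1.0;
      else if (si == score[j]) { c = 0.5; tied += 1.0; }
      else c = 0.0;
      conc += c; usable += 1.0;
      Pi[i] += c; Qi[i] += 1.0;
      Pi[j] += c; Qi[j] += 1.0;
    }
  }
  return List::create(_["concordant"] = conc, _["usable"] = usable,
                      _["tied_score"] = tied, _["P_i"] = Pi, _["Q_i"] = Qi);
}

// Fast counts-only version via a Fenwick tree over score ranks,
// O(n log n); same usable-pair rule as above.  Used where only the C
// value is needed (bootstrap resampling); equality with concordance_cpp
// is asserted in the test suite.

// [[Rcpp::export]]
List concordance_counts_cpp(NumericVector time, IntegerVector status,
                            NumericVector score) {
  const int n = time.size();
  // compress scores to ranks 1..m
  std::vector<int> ord(n), rank_of(n);
  for (int i = 0; i < n; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return score[a] < score[b]; });
  int m = 0;
  for (int k = 0; k < n; k++) {
    if (k > 0 && score[ord[k]] != score[ord[k - 1]]) m++;
    rank_of[ord[k]] = m + 1;
  }
  m++;
  std::vector<double> bit((size_t)m + 1, 0.0);
  double total_in = 0.0;
  auto add = [&](int r) {
    for (; r <= m; r += r & (-r)) bit[r] += 1.0;
    total_in += 1.0;
  };
  auto prefix = [&](int r) {        // count of ranks <= r
    double s = 0.0;
    for (; r > 0; r -= r & (-r)) s += bit[r];
    return s;
  };
  // subjects in decreasing time order, grouped by tied time
  std::vector<int> byt(n);
  for (int i = 0; i < n; i++) byt[i] = i;
  std::sort(byt.begin(), byt.end(),
            [&](int a, int b) { return time[a] > time[b]; });
  double conc = 0.0, usable = 0.0, tied = 0.0;
  int k = 0;
  while (k < n) {
    int k2 = k;
    while (k2 < n && time[byt[k2]] == time[byt[k]]) k2++;
    // censored members of this tied-time group join the partner pool first
    for (int q = k; q < k2; q++)
      if (status[byt[q]] == 0) add(rank_of[byt[q]]);
    for (int q = k; q < k2; q++) {
      const int i = byt[q];
      if (status[i] != 1) continue;
      const int r = rank_of[i];
      const double lower = prefix(r - 1);          // partners with lower score
      const double eq = prefix(r) - lower;         // tied scores
      conc += lower + 0.5 * eq;
      tied += eq;
      usable += total_in;
    }
    for (int q = k; q < k2; q++)
      if (status[byt[q]] == 1) add(rank_of[byt[q]]);
    k = k2;
  }
  return List::create(_["concordant"] = conc, _["usable"] = usable,
                      _["tied_score"] = tied);
}
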