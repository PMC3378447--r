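#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted Cox proportional-hazards fit, Breslow tie handling, optional
// staggered entry (risk set at t = {j : entry_j < t <= exit_j}).
// Input must be sorted by increasing exit time.  Weight-0 rows should be
// dropped by the caller.

// Gauss-Jordan inverse with partial pivoting; A row-major p x p.
static bool invert_matrix(const std::vector<double>& A, int p,
                          std::vector<double>& Ainv) {
  std::vector<double> M(A);
  Ainv.assign((size_t)p * p, 0.0);
  for (int i = 0; i < p; i++) Ainv[(size_t)i * p + i] = 1.0;
  for (int col = 0; col < p; col++) {
    int piv = col;
    double best = std::fabs(M[(size_t)col * p + col]);
    for (int r = col + 1; r < p; r++) {
      double v = std::fabs(M[(size_t)r * p + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-300) return false;
    if (piv != col) {
      for (int c = 0; c < p; c++) {
        std::swap(M[(size_t)piv * p + c], M[(size_t)col * p + c]);
        std::swap(Ainv[(size_t)piv * p + c], Ainv[(size_t)col * p + c]);
      }
    }
    double d = M[(size_t)col * p + col];
    for (int c = 0; c < p; c++) {
      M[(size_t)col * p + c] /= d;
      Ainv[(size_t)col * p + c] /= d;
    }
    for (int r = 0; r < p; r++) {
      if (r == col) continue;
      double f = M[(size_t)r * p + col];
      if (f == 0.0) continue;
      for (int c = 0; c < p; c++) {
        M[(size_t)r * p + c] -= f * M[(size_t)col * p + c];
        Ainv[(size_t)r * p + c] -= f * Ainv[(size_t)col * p + c];
      }
    }
  }
  return true;
}

// One evaluation of the weighted log partial likelihood plus score and
// information at beta.  exit ascending; ord_entry: indices sorted by
// decreasing entry time.  Returns loglik.
static double eval_partial(const NumericVector& exit_, const NumericVector& entry,
                           const IntegerVector& status, const NumericMatrix& X,
                           const NumericVector& w, const std::vector<double>& beta,
                           const std::vector<int>& ord_entry, bool has_entry,
                           std::vector<double>& score, std::vector<double>& info) {
  const int n = exit_.size(), p = X.ncol();
  std::fill(score.begin(), score.end(), 0.0);
  std::fill(info.begin(), info.end(), 0.0);
  double ll = 0.0;
  std::vector<double> risk(n);
  for (int i = 0; i < n; i++) {
    double e = 0.0;
    for (int k = 0; k < p; k++) e += X(i, k) * beta[k];
    risk[i] = w[i] * std::exp(e);
  }
  // running sums over {exit >= t} minus {entry >= t}
  double S0 = 0.0;
  std::vector<double> S1(p, 0.0), S2((size_t)p * p, 0.0);
  int ient = 0; // pointer into ord_entry (decreasing entry)
  int i = n - 1;
  while (i >= 0) {
    const double t = exit_[i];
    int j = i;
    while (j >= 0 && exit_[j] == t) {
      const double r = risk[j];
      S0 += r;
      for (int k = 0; k < p; k++) {
        const double rk = r * X(j, k);
        S1[k] += rk;
        for (int l = k; l < p; l++) S2[(size_t)k * p + l] += rk * X(j, l);
      }
      j--;
    }
    if (has_entry) {
      // remove subjects whose entry >= t (not yet at risk at t)
      while (ient < n && entry[ord_entry[ient]] >= t) {
        const int q = ord_entry[ient];
        const double r = risk[q];
        S0 -= r;
        for (int k = 0; k < p; k++) {
          const double rk = r * X(q, k);
          S1[k] -= rk;
          for (int l = k; l < p; l++) S2[(size_t)k * p + l] -= rk * X(q, l);
        }
        ient++;
      }
    }
    for (int m = i; m > j; m--) {
      if (status[m] == 1 && w[m] > 0) {
        double eta = 0.0;
        for (int k = 0; k < p; k++) eta += X(m, k) * beta[k];
        ll += w[m] * (eta - std::log(S0));
        for (int k = 0; k < p; k++) {
          const double xb = S1[k] / S0;
          score[k] += w[m] * (X(m, k) - xb);
          for (int l = k; l < p; l++)
            info[(size_t)k * p + l] +=
              w[m] * (S2[(size_t)k * p + l] / S0 - xb * S1[l] / S0);
        }
      }
    }
    i = j;
  }
  for (int k = 0; k < p; k++)
    for (int l = 0; l < k; l++) info[(size_t)k * p + l] = info[(size_t)l * p + k];
  return ll;
}

// [[Rcpp::export]]
List cox_fit_cpp(NumericVector exit_, NumericVector entry, IntegerVector status,
                 NumericMatrix X, NumericVector w, bool has_entry,
                 NumericVector init, bool minimal = false,
                 int max_iter = 25, double tol_score = 1e-8,
                 double tol_loglik = 1e-10) {
  const int n = exit_.size(), p = X.ncol();
  std::vector<int> ord_entry(n);
  for (int i = 0; i < n; i++) ord_entry[i] = i;
  if (has_entry)
    std::sort(ord_entry.begin(), ord_entry.end(),
              [&](int a, int b) { return entry[a] > entry[b]; });

  std::vector<double> beta(p, 0.0), score(p), info((size_t)p * p);
  if (init.size() == p)
    for (int k = 0; k < p; k++) beta[k] = init[k];
  std::vector<double> score_new(p), info_new((size_t)p * p), infoinv((size_t)p * p);
  double ll = eval_partial(exit_, entry, status, X, w, beta, ord_entry, has_entry,
                           score, info);
  const double loglik0 = ll;
  bool conv = false, singular = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; iter++) {
    double maxsc = 0.0;
    for (int k = 0; k < p; k++) maxsc = std::max(maxsc, std::fabs(score[k]));
    if (maxsc < tol_score) { conv = true; break; }
    if (!invert_matrix(info, p, infoinv)) { singular = true; break; }
    std::vector<double> step(p, 0.0);
    for (int k = 0; k < p; k++)
      for (int l = 0; l < p; l++) step[k] += infoinv[(size_t)k * p + l] * score[l];
    double f = 1.0, llnew = R_NegInf;
    std::vector<double> bnew(p);
    bool ok = false;
    for (int h = 0; h < 30; h++) {
      for (int k = 0; k < p; k++) bnew[k] = beta[k] + f * step[k];
      llnew = eval_partial(exit_, entry, status, X, w, bnew, ord_entry, has_entry,
                           score_new, info_new);
      if (R_finite(llnew) && llnew >= ll - 1e-12) { ok = true; break; }
      f /= 2.0;
    }
    if (!ok) break;
    const double rel = std::fabs(llnew - ll) / (std::fabs(ll) + 1.0);
    beta = bnew; ll = llnew; score = score_new; info = info_new;
    if (rel < tol_loglik) { conv = true; break; }
  }
  if (!singular) singular = !invert_matrix(info, p, infoinv);

  NumericVector coef(p);
  NumericMatrix var_model(p, p);
  for (int k = 0; k < p; k++) {
    coef[k] = beta[k];
    for (int l = 0; l < p; l++) var_model(k, l) = infoinv[(size_t)k * p + l];
  }

  if (minimal) {
    // coefficient-only fit (bootstrap resamples): skip residuals, robust
    // covariance and the baseline
    int n_events = 0;
    for (int i = 0; i < n; i++) if (status[i] == 1) n_events++;
    NumericVector lp(n);
    for (int i = 0; i < n; i++) {
      double e = 0.0;
      for (int k = 0; k < p; k++) e += X(i, k) * beta[k];
      lp[i] = e;
    }
    NumericVector score_out0(p);
    for (int k = 0; k < p; k++) score_out0[k] = score[k];
    return List::create(
      _["coef"] = coef, _["var_model"] = var_model,
      _["var_robust"] = var_model, _["loglik"] = ll, _["loglik0"] = loglik0,
      _["score"] = score_out0, _["iter"] = iter,
      _["converged"] = conv && !singular, _["singular"] = singular,
      _["base_time"] = NumericVector(0), _["base_haz"] = NumericVector(0),
      _["lp"] = lp, _["dfbeta"] = R_NilValue, _["n_events"] = n_events);
  }

  // --- event-time summaries at the solution (for residuals + baseline) ---
  std::vector<double> risk(n), eta(n);
  for (int i = 0; i < n; i++) {
    double e = 0.0;
    for (int k = 0; k < p; k++) e += X(i, k) * beta[k];
    eta[i] = e;
    risk[i] = w[i] * std::exp(e);
  }
  std::vector<double> et, eS0, ewd;   // unique event times (descending first)
  std::vector<double> exbar;          // p per event time
  {
    double S0 = 0.0;
    std::vector<double> S1(p, 0.0);
    int ient = 0;
    int i = n - 1;
    while (i >= 0) {
      const double t = exit_[i];
      int j = i;
      while (j >= 0 && exit_[j] == t) {
        S0 += risk[j];
        for (int k = 0; k < p; k++) S1[k] += risk[j] * X(j, k);
        j--;
      }
      if (has_entry) {
        while (ient < n && entry[ord_entry[ient]] >= t) {
          const int q = ord_entry[ient];
          S0 -= risk[q];
          for (int k = 0; k < p; k++) S1[k] -= risk[q] * X(q, k);
          ient++;
        }
      }
      double wd = 0.0;
      for (int m = i; m > j; m--)
        if (status[m] == 1) wd += w[m];
      if (wd > 0.0) {
        et.push_back(t);
        eS0.push_back(S0);
        ewd.push_back(wd);
        for (int k = 0; k < p; k++) exbar.push_back(S1[k] / S0);
      }
      i = j;
    }
    // flip to ascending
    std::reverse(et.begin(), et.end());
    std::reverse(eS0.begin(), eS0.end());
    std::reverse(ewd.begin(), ewd.end());
    std::vector<double> tmp(exbar.size());
    const int D = (int)et.size();
    for (int d = 0; d < D; d++)
      for (int k = 0; k < p; k++)
        tmp[(size_t)d * p + k] = exbar[(size_t)(D - 1 - d) * p + k];
    exbar.swap(tmp);
  }
  const int D = (int)et.size();
  NumericVector base_time(D), base_haz(D);
  std::vector<double> cum0(D + 1, 0.0), cumv((size_t)(D + 1) * p, 0.0);
  for (int d = 0; d < D; d++) {
    const double h = ewd[d] / eS0[d];
    base_time[d] = et[d];
    base_haz[d] = h;
    cum0[d + 1] = cum0[d] + h;
    for (int k = 0; k < p; k++)
      cumv[(size_t)(d + 1) * p + k] = cumv[(size_t)d * p + k] + h * exbar[(size_t)d * p + k];
  }

  // score residuals U_i and dfbeta_i = w_i U_i %*% infoinv
  NumericMatrix dfbeta(n, p);
  NumericMatrix var_robust(p, p);
  {
    // number of event times <= t via binary search
    auto n_le = [&](double t) {
      return (int)(std::upper_bound(et.begin(), et.end(), t) - et.begin());
    };
    std::vector<double> U(p);
    for (int i = 0; i < n; i++) {
      const int khi = n_le(exit_[i]);
      const int klo = has_entry ? n_le(entry[i]) : 0;
      const double ex = std::exp(eta[i]);
      for (int k = 0; k < p; k++) {
        double u = -ex * (X(i, k) * (cum0[khi] - cum0[klo]) -
                          (cumv[(size_t)khi * p + k] - cumv[(size_t)klo * p + k]));
        U[k] = u;
      }
      if (status[i] == 1 && khi > 0 && et[khi - 1] == exit_[i]) {
        for (int k = 0; k < p; k++)
          U[k] += X(i, k) - exbar[(size_t)(khi - 1) * p + k];
      }
      for (int k = 0; k < p; k++) {
        double d = 0.0;
        for (int l = 0; l < p; l++) d += w[i] * U[l] * infoinv[(size_t)l * p + k];
        dfbeta(i, k) = d;
      }
    }
    for (int k = 0; k < p; k++)
      for (int l = 0; l < p; l++) {
        double s = 0.0;
        for (int i = 0; i < n; i++) s += dfbeta(i, k) * dfbeta(i, l);
        var_robust(k, l) = s;
      }
  }

  int n_events = 0;
  for (int i = 0; i < n; i++) if (status[i] == 1) n_events++;
  NumericVector lp(n);
  for (int i = 0; i < n; i++) lp[i] = eta[i];
  NumericVector score_out(p);
  for (int k = 0; k < p; k++) score_out[k] = score[k];

  return List::create(
    _["coef"] = coef, _["var_model"] = var_model, _["var_robust"] = var_robust,
    _["loglik"] = ll, _["loglik0"] = loglik0, _["score"] = score_out,
    _["iter"] = iter, _["converged"] = conv && !singular,
    _["singular"] = singular,
    _["base_time"] = base_time, _["base_haz"] = base_haz,
    _["lp"] = lp, _["dfbeta"] = dfbeta, _["n_events"] = n_events);
}
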