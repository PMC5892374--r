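#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <map>
using namespace Rcpp;

// Theil-Sen estimator: slope = median of all pairwise slopes (t_i != t_j),
// intercept = median of (y_i - slope * (t_i - ref_year)), i.e. the fitted
// level at the reference year. The (1 - alpha) CI of the slope uses the
// rank-based Sen/Kendall procedure: with N pairwise slopes and
// var(S) = n(n-1)(2n+5)/18 corrected for tied times, the CI bounds are the
// slopes of rank (N - C)/2 and (N + C)/2 + 1, C = z_{1-alpha/2} * sqrt(var(S)).

static double median_of(std::vector<double>& v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// [[Rcpp::export]]
NumericVector cpp_theil_sen(NumericVector t, NumericVector y,
                            double ref_year, double alpha) {
  int n = t.size();
  NumericVector out = NumericVector::create(
      _["slope"] = NA_REAL, _["intercept"] = NA_REAL,
      _["ci_low"] = NA_REAL, _["ci_high"] = NA_REAL, _["n_pairs"] = 0.0);
  if (n < 2) return out;

  std::vector<double> slopes;
  slopes.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (t[j] != t[i]) slopes.push_back((y[j] - y[i]) / (t[j] - t[i]));
  size_t N = slopes.size();
  out["n_pairs"] = (double)N;
  if (N == 0) return out;

  std::vector<double> tmp(slopes);
  double slope = median_of(tmp);
  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - slope * (t[i] - ref_year);
  double intercept = median_of(resid);
  out["slope"] = slope;
  out["intercept"] = intercept;

  // Kendall S variance with correction for tied times
  std::map<double, int> ties;
  for (int i = 0; i < n; ++i) ties[t[i]]++;
  double varS = (double)n * (n - 1) * (2.0 * n + 5) / 18.0;
  for (auto& kv : ties) {
    double tp = kv.second;
    if (tp > 1) varS -= tp * (tp - 1) * (2.0 * tp + 5) / 18.0;
  }
  if (varS > 0 && N > 1) {
    double z = R::qnorm(1.0 - alpha / 2.0, 0.0, 1.0, 1, 0);
    double C = z * std::sqrt(varS);
    std::sort(slopes.begin(), slopes.end());
    long r1 = (long)std::lround(((double)N - C) / 2.0);
    long r2 = (long)std::lround(((double)N + C) / 2.0) + 1;
    if (r1 < 1) r1 = 1;
    if (r2 > (long)N) r2 = (long)N;
    out["ci_low"] = slopes[r1 - 1];
    out["ci_high"] = slopes[r2 - 1];
  } else {
    out["ci_low"] = slope;
    out["ci_high"] = slope;
  }
  return out;
}

// Per-pixel Theil-Sen over a time stack. `values` is nr*nc x nt (pixels in
// column-major grid order), `valid` the matching logical matrix, `times` the
// decimal-year axis. Pixels with fewer than min_obs valid observations (or
// fewer than 2 distinct times) yield NA.
// [[Rcpp::export]]
NumericMatrix cpp_trend_stack(NumericMatrix values, LogicalMatrix valid,
                              NumericVector times, double ref_year,
                              double alpha, int min_obs) {
  int np = values.nrow(), nt = values.ncol();
  NumericMatrix out(np, 5); // slope, intercept, ci_high, ci_low, count
  std::vector<double> tt, yy;
  for (int p = 0; p < np; ++p) {
    tt.clear();
    yy.clear();
    for (int k = 0; k < nt; ++k) {
      if (valid(p, k) && NumericVector::is_na(values(p, k)) == false) {
        tt.push_back(times[k]);
        yy.push_back(values(p, k));
      }
    }
    out(p, 4) = (double)tt.size();
    if ((int)tt.size() < min_obs || tt.size() < 2) {
      out(p, 0) = out(p, 1) = out(p, 2) = out(p, 3) = NA_REAL;
      continue;
    }
    NumericVector res = cpp_theil_sen(wrap(tt), wrap(yy), ref_year, alpha);
    out(p, 0) = res["slope"];
    out(p, 1) = res["intercept"];
    out(p, 2) = res["ci_high"];
    out(p, 3) = res["ci_low"];
    if (NumericVector::is_na(out(p, 0))) out(p, 2) = out(p, 3) = NA_REAL;
  }
  return out;
}
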