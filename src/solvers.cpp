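// Exact dynamic-programming changepoint solvers, Gaussian change-in-mean
// loss with unit variance (callers rescale the data for other sigma).
//
// Penalised problem:   F(t) = min_{0<=tau<t} F(tau) + C(y_{tau+1:t}) + beta,
//                      F(0) = -beta.
// Constrained problem: C_{k,t} = min_{k<=tau<=t-1} C_{k-1,tau} + C(y_{tau+1:t}),
//                      C_{0,t} = C(y_{1:t}).
//
// All argmin ties are broken toward the smallest tau. candidate_counts[t]
// records the size of the candidate set the minimisation at time t ran over
// (t itself for the unpruned solvers).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// O(1) segment costs from prefix sums; segment y_{(s+1):t}, 0 <= s < t <= n.
struct Prefix {
  std::vector<double> cs, css;
  explicit Prefix(const NumericVector& y) {
    int n = y.size();
    cs.resize(n + 1); css.resize(n + 1);
    cs[0] = 0.0; css[0] = 0.0;
    for (int i = 0; i < n; ++i) {
      cs[i + 1] = cs[i] + y[i];
      css[i + 1] = css[i] + y[i] * y[i];
    }
  }
  inline double cost(int s, int t) const {
    double S = cs[t] - cs[s];
    double SS = css[t] - css[s];
    double c = 0.5 * (SS - S * S / (double)(t - s));
    return c > 0.0 ? c : 0.0;
  }
};

// ---------------------------------------------------------------- penalised

// [[Rcpp::export(name = ".op_gauss")]]
List op_gauss(NumericVector y, double beta) {
  int n = y.size();
  Prefix p(y);
  NumericVector F(n + 1);
  IntegerVector lc(n), counts(n);
  F[0] = -beta;
  for (int t = 1; t <= n; ++t) {
    double best = INF; int arg = 0;
    for (int tau = 0; tau < t; ++tau) {
      double v = F[tau] + p.cost(tau, t) + beta;
      if (v < best) { best = v; arg = tau; }
    }
    F[t] = best; lc[t - 1] = arg; counts[t - 1] = t;
  }
  return List::create(_["F"] = F, _["last_change"] = lc,
                      _["candidate_counts"] = counts);
}

// [[Rcpp::export(name = ".pelt_gauss")]]
List pelt_gauss(NumericVector y, double beta, double kappa, bool trace) {
  int n = y.size();
  Prefix p(y);
  NumericVector F(n + 1);
  IntegerVector lc(n), counts(n);
  F[0] = -beta;
  std::vector<int> R; R.push_back(0);
  List sets(trace ? n : 0);
  std::vector<double> vals;
  for (int t = 1; t <= n; ++t) {
    counts[t - 1] = (int)R.size();
    if (trace) sets[t - 1] = IntegerVector(R.begin(), R.end());
    vals.resize(R.size());
    double best = INF; int arg = 0;
    for (size_t i = 0; i < R.size(); ++i) {
      double v = F[R[i]] + p.cost(R[i], t) + beta;
      vals[i] = v;
      if (v < best) { best = v; arg = R[i]; }
    }
    F[t] = best; lc[t - 1] = arg;
    // Inequality pruning: keep tau with F(tau) + C(y_{tau+1:t}) + kappa <= F(t);
    // the new candidate t satisfies the condition with equality (kappa = 0)
    // and is always admitted.
    std::vector<int> keep;
    keep.reserve(R.size() + 1);
    for (size_t i = 0; i < R.size(); ++i)
      if (vals[i] - beta + kappa <= F[t]) keep.push_back(R[i]);
    keep.push_back(t);
    R.swap(keep);
  }
  return List::create(_["F"] = F, _["last_change"] = lc,
                      _["candidate_counts"] = counts, _["sets"] = sets);
}

// One candidate cost function for functional pruning: quadratic
// a*mu^2 + b*mu + c on a union of disjoint closed intervals.
struct Cand {
  int tau;
  double a, b, c;
  std::vector<std::pair<double, double>> set;
};

static inline double vertex_value(const Cand& cd) {
  return cd.a > 0.0 ? cd.c - cd.b * cd.b / (4.0 * cd.a) : cd.c;
}

// level interval {mu : a mu^2 + b mu + c <= thr}; returns false if empty
static inline bool level_interval(const Cand& cd, double thr,
                                  double& lo, double& hi) {
  if (cd.a <= 0.0) {
    if (cd.c <= thr) { lo = -INF; hi = INF; return true; }
    return false;
  }
  double disc = cd.b * cd.b - 4.0 * cd.a * (cd.c - thr);
  if (disc < 0.0) return false;
  double r = std::sqrt(disc);
  lo = (-cd.b - r) / (2.0 * cd.a);
  hi = (-cd.b + r) / (2.0 * cd.a);
  return true;
}

// intersect candidate set with [lo, hi] in place; returns true if non-empty
static inline bool clip_set(Cand& cd, double lo, double hi) {
  std::vector<std::pair<double, double>> out;
  out.reserve(cd.set.size());
  for (auto& iv : cd.set) {
    double l = std::max(iv.first, lo), h = std::min(iv.second, hi);
    if (l <= h) out.emplace_back(l, h);
  }
  cd.set.swap(out);
  return !cd.set.empty();
}

// complement of the union of [lo_i, hi_i] within (-Inf, Inf); the level
// intervals of quadratics with a > 0 are bounded so the two tails survive.
static std::vector<std::pair<double, double>> complement_union(
    std::vector<std::pair<double, double>> ivs) {
  std::vector<std::pair<double, double>> out;
  if (ivs.empty()) { out.emplace_back(-INF, INF); return out; }
  std::sort(ivs.begin(), ivs.end());
  std::vector<std::pair<double, double>> merged;
  merged.push_back(ivs[0]);
  for (size_t i = 1; i < ivs.size(); ++i) {
    if (ivs[i].first <= merged.back().second)
      merged.back().second = std::max(merged.back().second, ivs[i].second);
    else
      merged.push_back(ivs[i]);
  }
  if (merged.front().first > -INF)
    out.emplace_back(-INF, merged.front().first);
  for (size_t i = 0; i + 1 < merged.size(); ++i)
    if (merged[i].second < merged[i + 1].first)
      out.emplace_back(merged[i].second, merged[i + 1].first);
  if (merged.back().second < INF)
    out.emplace_back(merged.back().second, INF);
  return out;
}

// [[Rcpp::export(name = ".fpop_gauss")]]
List fpop_gauss(NumericVector y, double beta, bool trace) {
  int n = y.size();
  NumericVector F(n + 1);
  IntegerVector lc(n), counts(n);
  F[0] = -beta;
  std::vector<Cand> cands;
  {
    Cand c0; c0.tau = 0; c0.a = 0.0; c0.b = 0.0; c0.c = F[0] + beta;
    c0.set.emplace_back(-INF, INF);
    cands.push_back(c0);
  }
  List sets(trace ? n : 0);
  for (int t = 1; t <= n; ++t) {
    double yt = y[t - 1];
    // absorb y_t into every live candidate's final segment
    for (auto& cd : cands) {
      cd.a += 0.5; cd.b += -yt; cd.c += 0.5 * yt * yt;
    }
    counts[t - 1] = (int)cands.size();
    if (trace) {
      IntegerVector s((int)cands.size());
      for (size_t i = 0; i < cands.size(); ++i) s[i] = cands[i].tau;
      sets[t - 1] = s;
    }
    // F(t) = min over live candidates of the unconstrained minimum
    double best = INF; int arg = 0;
    for (auto& cd : cands) {
      double v = vertex_value(cd);
      if (v < best) { best = v; arg = cd.tau; }
    }
    F[t] = best; lc[t - 1] = arg;
    // level intervals at threshold F(t) + beta; prune empty sets
    double thr = F[t] + beta;
    std::vector<std::pair<double, double>> level;
    level.reserve(cands.size());
    std::vector<Cand> alive;
    alive.reserve(cands.size() + 1);
    for (auto& cd : cands) {
      double lo, hi;
      if (!level_interval(cd, thr, lo, hi)) continue;  // set becomes empty
      level.emplace_back(lo, hi);
      if (clip_set(cd, lo, hi)) alive.push_back(std::move(cd));
    }
    // new candidate tau = t on the complement of the union
    if (t < n) {
      Cand nc; nc.tau = t; nc.a = 0.0; nc.b = 0.0; nc.c = F[t] + beta;
      nc.set = complement_union(level);
      if (!nc.set.empty()) alive.push_back(std::move(nc));
    }
    cands.swap(alive);
  }
  return List::create(_["F"] = F, _["last_change"] = lc,
                      _["candidate_counts"] = counts, _["sets"] = sets);
}

// -------------------------------------------------------------- constrained

// [[Rcpp::export(name = ".segneigh_gauss")]]
List segneigh_gauss(NumericVector y, int K) {
  int n = y.size();
  Prefix p(y);
  NumericMatrix C(K + 1, n + 1);
  IntegerMatrix bp(K + 1, n + 1);
  IntegerMatrix counts(K + 1, n + 1);
  std::fill(C.begin(), C.end(), NA_REAL);
  std::fill(bp.begin(), bp.end(), NA_INTEGER);
  std::fill(counts.begin(), counts.end(), NA_INTEGER);
  C(0, 0) = 0.0;
  for (int t = 1; t <= n; ++t) C(0, t) = p.cost(0, t);
  for (int k = 1; k <= K; ++k) {
    C(k, k) = 0.0;
    for (int t = k + 1; t <= n; ++t) {
      double best = INF; int arg = k;
      for (int tau = k; tau <= t - 1; ++tau) {
        double v = C(k - 1, tau) + p.cost(tau, t);
        if (v < best) { best = v; arg = tau; }
      }
      C(k, t) = best; bp(k, t) = arg; counts(k, t) = t - k;
    }
  }
  return List::create(_["C"] = C, _["backpointers"] = bp,
                      _["candidate_counts"] = counts);
}

// [[Rcpp::export(name = ".snip_gauss")]]
List snip_gauss(NumericVector y, int K, double kappa, bool trace) {
  int n = y.size();
  Prefix p(y);
  NumericMatrix C(K + 1, n + 1);
  IntegerMatrix bp(K + 1, n + 1);
  IntegerMatrix counts(K + 1, n + 1);
  std::fill(C.begin(), C.end(), NA_REAL);
  std::fill(bp.begin(), bp.end(), NA_INTEGER);
  std::fill(counts.begin(), counts.end(), NA_INTEGER);
  C(0, 0) = 0.0;
  for (int t = 1; t <= n; ++t) C(0, t) = p.cost(0, t);
  List sets(trace ? K : 0);
  for (int k = 1; k <= K; ++k) {
    C(k, k) = 0.0;
    std::vector<int> R; R.push_back(k);
    List ksets(trace ? (n - k) : 0);
    std::vector<double> base(R.size());
    for (int t = k + 1; t <= n; ++t) {
      counts(k, t) = (int)R.size();
      if (trace) ksets[t - k - 1] = IntegerVector(R.begin(), R.end());
      double best = INF; int arg = R[0];
      base.resize(R.size());
      for (size_t i = 0; i < R.size(); ++i) {
        double v = C(k - 1, R[i]) + p.cost(R[i], t);
        base[i] = v;
        if (v < best) { best = v; arg = R[i]; }
      }
      C(k, t) = best; bp(k, t) = arg;
      // Keep v with C_{k-1,v} + C(y_{v+1:t}) + kappa < C_{k-1,t}; the new
      // candidate t is always admitted (its condition is degenerate).
      std::vector<int> keep;
      keep.reserve(R.size() + 1);
      double bound = C(k - 1, t);
      for (size_t i = 0; i < R.size(); ++i)
        if (base[i] + kappa < bound) keep.push_back(R[i]);
      keep.push_back(t);
      R.swap(keep);
    }
    if (trace) sets[k - 1] = ksets;
  }
  return List::create(_["C"] = C, _["backpointers"] = bp,
                      _["candidate_counts"] = counts, _["sets"] = sets);
}

// One pDPA row (fixed k): returns C(k, t) for t = k+1..n given row k-1.
// Mirrors the FPOP step with threshold C_{k-1,t} in place of F(t) + beta.
static void pdpa_row(const NumericVector& y, int k, int n,
                     const double* Cprev, double* Crow, int* bprow,
                     int* countrow, List* ksets,
                     std::vector<std::vector<int>>* live_out) {
  std::vector<Cand> cands;
  Cand c0; c0.tau = k; c0.a = 0.0; c0.b = 0.0; c0.c = Cprev[k];
  c0.set.emplace_back(-INF, INF);
  cands.push_back(c0);
  for (int t = k + 1; t <= n; ++t) {
    double yt = y[t - 1];
    for (auto& cd : cands) {
      cd.a += 0.5; cd.b += -yt; cd.c += 0.5 * yt * yt;
    }
    countrow[t] = (int)cands.size();
    if (ksets) {
      IntegerVector s((int)cands.size());
      for (size_t i = 0; i < cands.size(); ++i) s[i] = cands[i].tau;
      (*ksets)[t - k - 1] = s;
    }
    if (live_out) {
      std::vector<int> taus(cands.size());
      for (size_t i = 0; i < cands.size(); ++i) taus[i] = cands[i].tau;
      (*live_out)[t - k - 1] = taus;
    }
    double best = INF; int arg = k;
    for (auto& cd : cands) {
      double v = vertex_value(cd);
      if (v < best) { best = v; arg = cd.tau; }
    }
    Crow[t] = best; bprow[t] = arg;
    double thr = Cprev[t];
    std::vector<std::pair<double, double>> level;
    level.reserve(cands.size());
    std::vector<Cand> alive;
    alive.reserve(cands.size() + 1);
    for (auto& cd : cands) {
      double lo, hi;
      if (!level_interval(cd, thr, lo, hi)) continue;
      level.emplace_back(lo, hi);
      if (clip_set(cd, lo, hi)) alive.push_back(std::move(cd));
    }
    if (t < n) {
      Cand nc; nc.tau = t; nc.a = 0.0; nc.b = 0.0; nc.c = thr;
      nc.set = complement_union(level);
      if (!nc.set.empty()) alive.push_back(std::move(nc));
    }
    cands.swap(alive);
  }
}

// [[Rcpp::export(name = ".pdpa_gauss")]]
List pdpa_gauss(NumericVector y, int K, bool trace) {
  int n = y.size();
  Prefix p(y);
  NumericMatrix C(K + 1, n + 1);
  IntegerMatrix bp(K + 1, n + 1);
  IntegerMatrix counts(K + 1, n + 1);
  std::fill(C.begin(), C.end(), NA_REAL);
  std::fill(bp.begin(), bp.end(), NA_INTEGER);
  std::fill(counts.begin(), counts.end(), NA_INTEGER);
  C(0, 0) = 0.0;
  for (int t = 1; t <= n; ++t) C(0, t) = p.cost(0, t);
  List sets(trace ? K : 0);
  std::vector<double> Cprev(n + 1), Crow(n + 1);
  std::vector<int> bprow(n + 1), countrow(n + 1);
  for (int k = 1; k <= K; ++k) {
    for (int t = 0; t <= n; ++t) Cprev[t] = C(k - 1, t);
    List ksets(trace ? (n - k) : 0);
    pdpa_row(y, k, n, Cprev.data(), Crow.data(), bprow.data(),
             countrow.data(), trace ? &ksets : nullptr, nullptr);
    C(k, k) = 0.0;
    for (int t = k + 1; t <= n; ++t) {
      C(k, t) = Crow[t]; bp(k, t) = bprow[t]; counts(k, t) = countrow[t];
    }
    if (trace) sets[k - 1] = ksets;
  }
  return List::create(_["C"] = C, _["backpointers"] = bp,
                      _["candidate_counts"] = counts, _["sets"] = sets);
}

// Lock-step dominance check (constrained problem): runs pDPA and SNIP rows
// side by side and verifies at every (k, t) that the functional-pruning
// candidate set is a subset of the inequality-pruning one, without storing
// the full traces. Returns the verdict plus per-(k,t) candidate counts.
// [[Rcpp::export(name = ".constrained_dominance_gauss")]]
List constrained_dominance_gauss(NumericVector y, int K, double kappa) {
  int n = y.size();
  Prefix p(y);
  // SNIP state uses its own C matrix; pDPA its own. They must agree.
  NumericMatrix Cs(K + 1, n + 1), Cp(K + 1, n + 1);
  IntegerMatrix counts_p(K + 1, n + 1), counts_s(K + 1, n + 1);
  std::fill(Cs.begin(), Cs.end(), NA_REAL);
  std::fill(Cp.begin(), Cp.end(), NA_REAL);
  std::fill(counts_p.begin(), counts_p.end(), NA_INTEGER);
  std::fill(counts_s.begin(), counts_s.end(), NA_INTEGER);
  Cs(0, 0) = 0.0; Cp(0, 0) = 0.0;
  for (int t = 1; t <= n; ++t) { Cs(0, t) = p.cost(0, t); Cp(0, t) = Cs(0, t); }
  bool ok = true;
  double max_cdiff = 0.0;
  for (int k = 1; k <= K && ok; ++k) {
    Cs(k, k) = 0.0; Cp(k, k) = 0.0;
    // SNIP row state
    std::vector<int> R; R.push_back(k);
    // pDPA row state
    std::vector<Cand> cands;
    Cand c0; c0.tau = k; c0.a = 0.0; c0.b = 0.0; c0.c = Cp(k - 1, k);
    c0.set.emplace_back(-INF, INF);
    cands.push_back(c0);
    std::vector<double> base;
    for (int t = k + 1; t <= n; ++t) {
      // --- pDPA step
      double yt = y[t - 1];
      for (auto& cd : cands) { cd.a += 0.5; cd.b += -yt; cd.c += 0.5 * yt * yt; }
      counts_p(k, t) = (int)cands.size();
      double bestp = INF;
      for (auto& cd : cands) {
        double v = vertex_value(cd);
        if (v < bestp) bestp = v;
      }
      Cp(k, t) = bestp;
      // --- SNIP step
      counts_s(k, t) = (int)R.size();
      base.resize(R.size());
      double bests = INF;
      for (size_t i = 0; i < R.size(); ++i) {
        double v = Cs(k - 1, R[i]) + p.cost(R[i], t);
        base[i] = v;
        if (v < bests) bests = v;
      }
      Cs(k, t) = bests;
      double d = std::fabs(bests - bestp);
      if (d > max_cdiff) max_cdiff = d;
      // --- subset check: live pDPA taus must all appear in R (both sorted)
      size_t j = 0;
      for (auto& cd : cands) {
        while (j < R.size() && R[j] < cd.tau) ++j;
        if (j == R.size() || R[j] != cd.tau) { ok = false; break; }
      }
      if (!ok) break;
      // --- SNIP prune
      std::vector<int> keep; keep.reserve(R.size() + 1);
      double bound = Cs(k - 1, t);
      for (size_t i = 0; i < R.size(); ++i)
        if (base[i] + kappa < bound) keep.push_back(R[i]);
      keep.push_back(t);
      R.swap(keep);
      // --- pDPA prune + new candidate
      double thr = Cp(k - 1, t);
      std::vector<std::pair<double, double>> level;
      level.reserve(cands.size());
      std::vector<Cand> alive; alive.reserve(cands.size() + 1);
      for (auto& cd : cands) {
        double lo, hi;
        if (!level_interval(cd, thr, lo, hi)) continue;
        level.emplace_back(lo, hi);
        if (clip_set(cd, lo, hi)) alive.push_back(std::move(cd));
      }
      if (t < n) {
        Cand nc; nc.tau = t; nc.a = 0.0; nc.b = 0.0; nc.c = thr;
        nc.set = complement_union(level);
        if (!nc.set.empty()) alive.push_back(std::move(nc));
      }
      cands.swap(alive);
    }
  }
  return List::create(_["ok"] = ok, _["max_c_diff"] = max_cdiff,
                      _["counts_functional"] = counts_p,
                      _["counts_inequality"] = counts_s);
}
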