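// Kendall tau-b statistics and the within-sample permutation engine for the
// evidence-pattern Monte-Carlo test. The engine permutes the outcome within
// each sample, recomputes every correlation cell with its frozen method tag
// and listwise mask, and counts runs whose evidence pattern is at least as
// strong as the observed one. Tie structure of the contact variables is
// permutation-invariant and precomputed; outcome-side tie terms are
// recomputed per run because listwise masks select different outcome values
// under permutation.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct TieTerms { double t1, t2, t3; };  // sum t(t-1)/2, t(t-1)(2t+5), t(t-1)(t-2)

static TieTerms tie_terms(std::vector<double> v) {
  std::sort(v.begin(), v.end());
  TieTerms tt = {0.0, 0.0, 0.0};
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    double t = static_cast<double>(j - i);
    tt.t1 += t * (t - 1) / 2.0;
    tt.t2 += t * (t - 1) * (2 * t + 5);
    tt.t3 += t * (t - 1) * (t - 2);
    i = j;
  }
  return tt;
}

static double concordance_S(const std::vector<double>& x,
                            const std::vector<double>& y) {
  const int n = static_cast<int>(x.size());
  double S = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double p = (x[i] - x[j]) * (y[i] - y[j]);
      if (p > 0) S += 1.0; else if (p < 0) S -= 1.0;
    }
  }
  return S;
}

// Tie-adjusted variance of S under random permutation (Kendall 1976).
static double var_S(int n, const TieTerms& tx, const TieTerms& ty) {
  double v = (n * (n - 1.0) * (2.0 * n + 5.0) - tx.t2 - ty.t2) / 18.0;
  if (n > 2) v += tx.t3 * ty.t3 / (9.0 * n * (n - 1.0) * (n - 2.0));
  v += 2.0 * tx.t1 * ty.t1 / (n * (n - 1.0));
  return v;
}

// [[Rcpp::export]]
List cpp_tau_b(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n != y.size()) stop("x and y lengths differ");
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  TieTerms tx = tie_terms(xv), ty = tie_terms(yv);
  const double n0 = n * (n - 1.0) / 2.0;
  const double denom = std::sqrt((n0 - tx.t1) * (n0 - ty.t1));
  if (denom <= 0) stop("all values tied on one variable");
  const double S = concordance_S(xv, yv);
  const double v = var_S(n, tx, ty);
  const double tau = S / denom;
  double p = 1.0;
  if (v > 0) {
    const double z = S / std::sqrt(v);
    p = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
    if (p > 1.0) p = 1.0;
  }
  return List::create(_["tau"] = tau, _["S"] = S, _["var_S"] = v,
                      _["p"] = p, _["n"] = n);
}

// Exact two-sided permutation p-value for tau-b, enumerating all distinct
// arrangements of y (multiset permutations are equiprobable under random
// assignment). Feasible for n <= 9.
// [[Rcpp::export]]
List cpp_tau_b_exact(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n != y.size()) stop("x and y lengths differ");
  if (n > 9) stop("exact enumeration supported only for n <= 9");
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  const double S_obs = std::fabs(concordance_S(xv, yv));
  std::vector<double> yp(yv);
  std::sort(yp.begin(), yp.end());
  double total = 0.0, hits = 0.0;
  const double eps = 1e-9;
  do {
    total += 1.0;
    if (std::fabs(concordance_S(xv, yp)) >= S_obs - eps) hits += 1.0;
  } while (std::next_permutation(yp.begin(), yp.end()));
  return List::create(_["p"] = hits / total, _["n_arrangements"] = total);
}

// --- deterministic counter-based RNG (splitmix64) --------------------------

static inline uint64_t splitmix64(uint64_t& s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Stream keyed by (seed, sample index, run index): identical results for a
// given seed regardless of execution order.
static inline uint64_t stream_key(uint64_t seed, uint64_t samp, uint64_t run) {
  uint64_t s = seed;
  uint64_t a = splitmix64(s) ^ (run * 0xD1342543DE82EF95ULL);
  uint64_t b = a;
  return splitmix64(b) ^ (samp * 0xC2B2AE3D27D4EB4FULL);
}

static void shuffle_idx(std::vector<int>& idx, uint64_t& state) {
  for (int i = static_cast<int>(idx.size()) - 1; i > 0; --i) {
    const int j = static_cast<int>(splitmix64(state) % (uint64_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// --- evidence patterns ------------------------------------------------------

struct Cell {
  std::vector<int> idx;      // 0-based positions into the sample outcome
  std::vector<double> x;     // contact values aligned with idx
  int method;                // 0 = pearson, 1 = tau_b
  int sign;                  // predicted sign, +1 / -1
  // precomputed for pearson
  std::vector<double> xc;    // centred x
  double ssx;
  // precomputed for tau (Knight's algorithm: x-order and x-tie groups fixed)
  TieTerms tx;
  double n0_minus_t1x;
  std::vector<int> xorder;   // positions sorted by x (stable)
  std::vector<int> xgroup;   // group starts, terminated by n
};

struct Workspace {
  std::vector<double> a, buf, ysort;
};

// merge-sort inversion count (strict left > right), sorts `a` ascending
static double count_inversions(std::vector<double>& a,
                               std::vector<double>& buf, int lo, int hi) {
  if (hi - lo < 2) return 0.0;
  const int mid = (lo + hi) / 2;
  double inv = count_inversions(a, buf, lo, mid) +
               count_inversions(a, buf, mid, hi);
  int i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (a[j] < a[i]) { inv += mid - i; buf[k++] = a[j++]; }
    else buf[k++] = a[i++];
  }
  while (i < mid) buf[k++] = a[i++];
  while (j < hi) buf[k++] = a[j++];
  for (int t = lo; t < hi; ++t) a[t] = buf[t];
  return inv;
}

static void score_cell(const Cell& c, const std::vector<double>& yfull,
                       double alpha_sig, double alpha_marg,
                       int& d, int& s, int& a_cnt, Workspace& ws,
                       double* est_out = nullptr, double* p_out = nullptr) {
  const int n = static_cast<int>(c.idx.size());
  double est = 0.0, p = 1.0;
  if (c.method == 0) {
    double my = 0.0;
    for (int k = 0; k < n; ++k) my += yfull[c.idx[k]];
    my /= n;
    double sxy = 0.0, ssy = 0.0;
    for (int k = 0; k < n; ++k) {
      const double dy = yfull[c.idx[k]] - my;
      sxy += c.xc[k] * dy;
      ssy += dy * dy;
    }
    if (ssy > 0 && c.ssx > 0) {
      est = sxy / std::sqrt(c.ssx * ssy);
      if (est > 1.0) est = 1.0; if (est < -1.0) est = -1.0;
      if (std::fabs(est) < 1.0) {
        const double t = est * std::sqrt((n - 2.0) / (1.0 - est * est));
        p = 2.0 * R::pt(-std::fabs(t), n - 2.0, 1, 0);
      } else {
        p = 0.0;
      }
    }
  } else {
    // Kendall tau-b via Knight's algorithm:
    //   S = n0 - t1x - t1y + joint_ties - 2 * discordant,
    // where discordant is the inversion count of y arranged in x-order with
    // y sorted ascending inside each x-tie group (so x-tied pairs drop out).
    std::vector<double>& a = ws.a;
    if ((int)a.size() < n) { a.resize(n); ws.buf.resize(n); ws.ysort.resize(n); }
    for (int k = 0; k < n; ++k) {
      a[k] = yfull[c.idx[c.xorder[k]]];
      ws.ysort[k] = a[k];
    }
    double joint = 0.0;
    for (size_t g = 0; g + 1 < c.xgroup.size(); ++g) {
      const int lo = c.xgroup[g], hi = c.xgroup[g + 1];
      if (hi - lo > 1) std::sort(a.begin() + lo, a.begin() + hi);
      int i = lo;
      while (i < hi) {
        int j = i;
        while (j < hi && a[j] == a[i]) ++j;
        const double t = j - i;
        joint += t * (t - 1) / 2.0;
        i = j;
      }
    }
    const double dis = count_inversions(a, ws.buf, 0, n);
    // y tie terms from a sorted copy
    std::sort(ws.ysort.begin(), ws.ysort.begin() + n);
    TieTerms ty = {0.0, 0.0, 0.0};
    {
      int i = 0;
      while (i < n) {
        int j = i;
        while (j < n && ws.ysort[j] == ws.ysort[i]) ++j;
        const double t = j - i;
        ty.t1 += t * (t - 1) / 2.0;
        ty.t2 += t * (t - 1) * (2 * t + 5);
        ty.t3 += t * (t - 1) * (t - 2);
        i = j;
      }
    }
    const double n0 = n * (n - 1.0) / 2.0;
    const double denom2 = c.n0_minus_t1x * (n0 - ty.t1);
    if (denom2 > 0) {
      const double S = n0 - c.tx.t1 - ty.t1 + joint - 2.0 * dis;
      est = S / std::sqrt(denom2);
      const double v = var_S(n, c.tx, ty);
      if (v > 0) {
        p = 2.0 * R::pnorm(-std::fabs(S) / std::sqrt(v), 0.0, 1.0, 1, 0);
        if (p > 1.0) p = 1.0;
      }
    }
  }
  const bool dir = (c.sign > 0 && est > 0) || (c.sign < 0 && est < 0);
  if (dir) {
    ++d;
    if (p < alpha_sig) ++s;
    else if (p < alpha_marg) ++a_cnt;
  }
  if (est_out) *est_out = est;
  if (p_out) *p_out = p;
}

static void prepare_cell(Cell& cell) {
  const int n = static_cast<int>(cell.x.size());
  double mx = 0.0;
  for (double v : cell.x) mx += v;
  mx /= n;
  cell.ssx = 0.0;
  cell.xc.resize(n);
  for (int k = 0; k < n; ++k) {
    cell.xc[k] = cell.x[k] - mx;
    cell.ssx += cell.xc[k] * cell.xc[k];
  }
  cell.tx = tie_terms(cell.x);
  cell.n0_minus_t1x = n * (n - 1.0) / 2.0 - cell.tx.t1;
  cell.xorder.resize(n);
  for (int k = 0; k < n; ++k) cell.xorder[k] = k;
  std::stable_sort(cell.xorder.begin(), cell.xorder.end(),
                   [&](int i, int j) { return cell.x[i] < cell.x[j]; });
  cell.xgroup.clear();
  for (int k = 0; k < n; ++k) {
    if (k == 0 || cell.x[cell.xorder[k]] != cell.x[cell.xorder[k - 1]]) {
      cell.xgroup.push_back(k);
    }
  }
  cell.xgroup.push_back(n);
}

static bool qualifies(int d, int s, int a, int od, int os, int oa,
                      int ordering) {
  switch (ordering) {
  case 0: return d >= od && s >= os;                       // ds dominance
  case 1: return d >= od && s >= os && (s + a) >= (os + oa); // dsa
  case 2: return d > od || (d == od && s >= os);           // lexicographic
  }
  return false;
}

// samples: list of list(y = numeric, cells = list of
//          list(idx = integer 0-based, x = numeric, method = int, sign = int))
// perms: R_NilValue for internal RNG, else list (per sample) of integer
//        matrices n_runs x n_i (0-based permutations), for oracle tests.
// [[Rcpp::export]]
List cpp_mc_evidence(List samples, int n_runs, double alpha_sig,
                     double alpha_marg, int obs_d, int obs_s, int obs_a,
                     int ordering, double seed, Nullable<List> perms,
                     bool keep_patterns) {
  const int n_samp = samples.size();
  std::vector<std::vector<double> > ys(n_samp);
  std::vector<std::vector<Cell> > cells(n_samp);
  for (int si = 0; si < n_samp; ++si) {
    List smp = samples[si];
    NumericVector y = smp["y"];
    ys[si].assign(y.begin(), y.end());
    List cl = smp["cells"];
    for (int ci = 0; ci < cl.size(); ++ci) {
      List c = cl[ci];
      Cell cell;
      IntegerVector idx = c["idx"];
      NumericVector x = c["x"];
      cell.idx.assign(idx.begin(), idx.end());
      cell.x.assign(x.begin(), x.end());
      cell.method = as<int>(c["method"]);
      cell.sign = as<int>(c["sign"]);
      if (cell.x.size() != cell.idx.size()) stop("idx/x length mismatch");
      prepare_cell(cell);
      cells[si].push_back(cell);
    }
  }

  bool use_given = perms.isNotNull();
  std::vector<IntegerMatrix> pm;
  if (use_given) {
    List pl(perms);
    if (pl.size() != n_samp) stop("perms must have one matrix per sample");
    for (int si = 0; si < n_samp; ++si) {
      IntegerMatrix m = pl[si];
      if (m.nrow() != n_runs) stop("perms rows must equal n_runs");
      if (m.ncol() != static_cast<int>(ys[si].size()))
        stop("perms cols must equal sample size");
      pm.push_back(m);
    }
  }

  const uint64_t useed = static_cast<uint64_t>(seed);
  int n_qual = 0;
  IntegerMatrix patterns(keep_patterns ? n_runs : 0, 3);
  std::vector<double> yperm;
  Workspace ws;
  std::vector<std::vector<int> > ident(n_samp);
  for (int si = 0; si < n_samp; ++si) {
    ident[si].resize(ys[si].size());
    for (size_t i = 0; i < ys[si].size(); ++i) ident[si][i] = (int)i;
  }

  for (int run = 0; run < n_runs; ++run) {
    int d = 0, s = 0, a = 0;
    for (int si = 0; si < n_samp; ++si) {
      const size_t n = ys[si].size();
      yperm.resize(n);
      if (use_given) {
        for (size_t i = 0; i < n; ++i) yperm[i] = ys[si][pm[si](run, i)];
      } else {
        std::vector<int> idx = ident[si];
        uint64_t state = stream_key(useed, (uint64_t)si, (uint64_t)run);
        shuffle_idx(idx, state);
        for (size_t i = 0; i < n; ++i) yperm[i] = ys[si][idx[i]];
      }
      for (const Cell& c : cells[si]) {
        score_cell(c, yperm, alpha_sig, alpha_marg, d, s, a, ws);
      }
    }
    if (qualifies(d, s, a, obs_d, obs_s, obs_a, ordering)) ++n_qual;
    if (keep_patterns) {
      patterns(run, 0) = d; patterns(run, 1) = s; patterns(run, 2) = a;
    }
    if ((run & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["n_qualifying"] = n_qual, _["n_runs"] = n_runs);
  if (keep_patterns) out["patterns"] = patterns;
  return out;
}

// Estimate and p-value for one cell via the engine's fast path (Knight
// inversion counting for tau); exposed so tests can check it against the
// brute-force pairwise route.
// [[Rcpp::export]]
List cpp_cell_stats(NumericVector x, NumericVector y, int method) {
  Cell cell;
  cell.x.assign(x.begin(), x.end());
  cell.idx.resize(x.size());
  for (int k = 0; k < x.size(); ++k) cell.idx[k] = k;
  cell.method = method;
  cell.sign = 1;
  prepare_cell(cell);
  std::vector<double> yv(y.begin(), y.end());
  Workspace ws;
  int d = 0, s = 0, a = 0;
  double est = 0.0, p = 1.0;
  score_cell(cell, yv, 0.05, 0.09, d, s, a, ws, &est, &p);
  return List::create(_["estimate"] = est, _["p"] = p);
}

// Evidence pattern for one explicit outcome assignment (used to verify that
// the identity permutation reproduces the observed pattern, and by the
// single-run R interface).
// [[Rcpp::export]]
List cpp_pattern_once(List samples, double alpha_sig, double alpha_marg) {
  int d = 0, s = 0, a = 0, m = 0;
  Workspace ws;
  for (int si = 0; si < samples.size(); ++si) {
    List smp = samples[si];
    NumericVector y = smp["y"];
    std::vector<double> yv(y.begin(), y.end());
    List cl = smp["cells"];
    for (int ci = 0; ci < cl.size(); ++ci) {
      List c = cl[ci];
      Cell cell;
      IntegerVector idx = c["idx"];
      NumericVector x = c["x"];
      cell.idx.assign(idx.begin(), idx.end());
      cell.x.assign(x.begin(), x.end());
      cell.method = as<int>(c["method"]);
      cell.sign = as<int>(c["sign"]);
      prepare_cell(cell);
      score_cell(cell, yv, alpha_sig, alpha_marg, d, s, a, ws);
      ++m;
    }
  }
  return List::create(_["m"] = m, _["d"] = d, _["s"] = s, _["a"] = a);
}
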