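// Exact depth-first branch-and-bound for the exclusivity-penalized
// weighted coverage objective, in the canonical maximize-U form:
//   U(M) = sum_{j in Gamma(M)} v_j - (c_j(M) - 1) * absdp_j
// where c_j counts penalty groups (a same-gene I/O pair is one group).
// Features are explored in the caller's order, include-branch first, and
// the incumbent is replaced only on strict (1e-9) improvement, so the
// first-found optimum respects the caller's tie-break order.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct BB {
  int m, n, k;
  const std::vector<std::vector<int>>* cov;   // 0-based sample indices
  std::vector<int> partner;                   // index of same-group mate or -1
  const double* v;
  const double* absdp;
  std::vector<double> suffix;                 // (m+1) x k best-suffix sums
  std::vector<int> cnt;                       // penalty groups covering sample
  std::vector<char> included;
  std::vector<int> cur, best;
  double curU = 0.0, bestU = 0.0;

  double suff(int r, int q) const { return suffix[(size_t)r * k + (q - 1)]; }

  void dfs(int r, int depth) {
    if (curU > bestU + 1e-9) { bestU = curU; best = cur; }
    if (r >= m || depth >= k) return;
    int slots = k - depth;
    if (curU + suff(r, slots) <= bestU + 1e-9) return;
    // include r
    const std::vector<int>& jj = (*cov)[r];
    int p = partner[r];
    bool skip_partner = (p >= 0 && included[p]);
    std::vector<int> newj;
    double dU = 0.0;
    if (skip_partner) {
      const std::vector<int>& pj = (*cov)[p];
      for (int j : jj) {
        if (std::find(pj.begin(), pj.end(), j) != pj.end()) continue;
        newj.push_back(j);
      }
    } else {
      newj.assign(jj.begin(), jj.end());
    }
    for (int j : newj) dU += (cnt[j] == 0) ? v[j] : -absdp[j];
    for (int j : newj) ++cnt[j];
    included[r] = 1; cur.push_back(r); curU += dU;
    dfs(r + 1, depth + 1);
    cur.pop_back(); curU -= dU; included[r] = 0;
    for (int j : newj) --cnt[j];
    // exclude r
    dfs(r + 1, depth);
  }
};

}  // namespace

// [[Rcpp::export(name = ".bb_solve_cpp")]]
List bb_solve_cpp(List cov1, IntegerVector grp, NumericVector v,
                  NumericVector absdp, int k, double init_U) {
  int m = cov1.size();
  int n = v.size();
  std::vector<std::vector<int>> cov(m);
  for (int i = 0; i < m; ++i) {
    IntegerVector ci = cov1[i];
    cov[i].assign(ci.begin(), ci.end());
    for (int& j : cov[i]) --j;  // to 0-based
  }
  BB bb;
  bb.m = m; bb.n = n; bb.k = std::min(k, m);
  bb.cov = &cov;
  bb.v = REAL(v);
  bb.absdp = REAL(absdp);
  // partner = the single other feature sharing a penalty group (or -1);
  // grouping guarantees at most two members per group
  bb.partner.assign(m, -1);
  {
    int mx = 0;
    for (int i = 0; i < m; ++i) mx = std::max(mx, grp[i]);
    std::vector<int> seen(mx + 1, -1);
    for (int i = 0; i < m; ++i) {
      int g = grp[i];
      if (seen[g] >= 0) { bb.partner[i] = seen[g]; bb.partner[seen[g]] = i; }
      seen[g] = i;
    }
  }
  // admissible bound: feature i adds at most its positive-v coverage mass
  std::vector<double> ub(m);
  for (int i = 0; i < m; ++i) {
    double s = 0;
    for (int j : cov[i]) if (bb.v[j] > 0) s += bb.v[j];
    ub[i] = s;
  }
  int K = bb.k;
  bb.suffix.assign((size_t)(m + 1) * K, 0.0);
  std::vector<double> top;  // positive ubs in suffix, kept sorted desc
  for (int r = m - 1; r >= 0; --r) {
    if (ub[r] > 0) {
      top.insert(std::upper_bound(top.begin(), top.end(), ub[r],
                                  std::greater<double>()), ub[r]);
      if ((int)top.size() > K) top.pop_back();
    }
    double acc = 0;
    for (int q = 0; q < K; ++q) {
      if (q < (int)top.size()) acc += top[q];
      bb.suffix[(size_t)r * K + q] = acc;
    }
  }
  bb.cnt.assign(n, 0);
  bb.included.assign(m, 0);
  // init_U > 0 seeds the incumbent: only sets beating it are sought
  // (used by permutation tests that just compare against a threshold)
  bb.bestU = std::max(0.0, init_U);
  bb.dfs(0, 0);
  IntegerVector idx(bb.best.size());
  for (size_t i = 0; i < bb.best.size(); ++i) idx[i] = bb.best[i] + 1;
  return List::create(_["idx"] = idx, _["U"] = bb.bestU);
}

// Curveball trades over row coverage lists: rows exchange a random split
// of their symmetric difference, preserving all row and column sums.
// [[Rcpp::export(name = ".curveball_cpp")]]
List curveball_cpp(List rows1, int n_trades) {
  int m = rows1.size();
  std::vector<std::vector<int>> rows(m);
  for (int i = 0; i < m; ++i) {
    IntegerVector ri = rows1[i];
    rows[i].assign(ri.begin(), ri.end());
  }
  if (m >= 2) {
    std::vector<char> inb;
    std::vector<int> a_only, b_only, ab;
    for (int t = 0; t < n_trades; ++t) {
      int r1 = (int)(unif_rand() * m);
      if (r1 >= m) r1 = m - 1;
      int r2 = (int)(unif_rand() * (m - 1));
      if (r2 >= m - 1) r2 = m - 2;
      if (r2 >= r1) ++r2;
      std::vector<int>& a = rows[r1];
      std::vector<int>& b = rows[r2];
      ab.clear(); a_only.clear(); b_only.clear();
      for (int x : a) {
        if (std::find(b.begin(), b.end(), x) != b.end()) ab.push_back(x);
        else a_only.push_back(x);
      }
      for (int x : b)
        if (std::find(a.begin(), a.end(), x) == a.end()) b_only.push_back(x);
      if (a_only.empty() || b_only.empty()) continue;
      std::vector<int> pool(a_only);
      pool.insert(pool.end(), b_only.begin(), b_only.end());
      // Fisher-Yates partial shuffle of the pool
      int na = (int)a_only.size();
      for (int i = 0; i < (int)pool.size() - 1; ++i) {
        int j = i + (int)(unif_rand() * (pool.size() - i));
        if (j >= (int)pool.size()) j = (int)pool.size() - 1;
        std::swap(pool[i], pool[j]);
      }
      a.assign(ab.begin(), ab.end());
      a.insert(a.end(), pool.begin(), pool.begin() + na);
      b.assign(ab.begin(), ab.end());
      b.insert(b.end(), pool.begin() + na, pool.end());
    }
  }
  List out(m);
  for (int i = 0; i < m; ++i) out[i] = IntegerVector(rows[i].begin(),
                                                     rows[i].end());
  return out;
}
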