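// Tail enumeration of 2^k contingency tables with fixed margins.
//
// Enumerates every table with T(Y) >= t_obs by assigning counts to the
// co-occurring cells (|v| >= 2) under the remaining co-occurrence budget and
// the remaining margins; singleton cells and the empty cell are then
// determined by the margins. Cells are visited in decreasing |v| so the
// heaviest budget consumers are pruned first.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

struct TailEnum {
  int k, n;
  long w_max;
  std::vector<std::vector<int>> members; // per co-occurring cell
  std::vector<int> csize;
  std::vector<double> lfac;              // lfac[x] = log(x!)
  std::vector<int> mar;                  // remaining margins
  double cst;                            // margin-dependent constant
  double eps;                            // stop when p_ge > eps (< 0: never)
  double p_ge = 0.0, p_gt = 0.0;
  double ntab = 0.0;
  bool stopped = false;

  void rec(std::size_t i, long w_rem, double lfy, int ysum) {
    if (stopped) return;
    if (i == members.size()) {
      int smar = 0;
      for (int j = 0; j < k; ++j) smar += mar[j];
      int x0 = n - ysum - smar;
      if (x0 < 0) return;
      double lp = cst - lfy - lfac[x0];
      for (int j = 0; j < k; ++j) lp -= lfac[mar[j]];
      double p = std::exp(lp);
      p_ge += p;
      if (w_rem > 0) p_gt += p; // T(Y) = t_obs + w_rem > t_obs
      ntab += 1.0;
      if (eps >= 0.0 && p_ge > eps) stopped = true;
      return;
    }
    const std::vector<int>& v = members[i];
    int sz = csize[i];
    long ub = w_rem / sz;
    for (std::size_t a = 0; a < v.size(); ++a)
      if (mar[v[a]] < ub) ub = mar[v[a]];
    for (long y = 0; y <= ub; ++y) {
      if (y > 0)
        for (std::size_t a = 0; a < v.size(); ++a) --mar[v[a]];
      rec(i + 1, w_rem - y * sz, lfy + lfac[y], ysum + (int)y);
      if (stopped) break;
    }
    // restore margins consumed by this cell
    long used = ub; // loop always ends with mar decremented ub times (or fewer if stopped)
    if (stopped) return; // caller unwinds; margins no longer needed
    for (std::size_t a = 0; a < v.size(); ++a) mar[v[a]] += (int)used;
  }
};

inline int popcount_int(unsigned x) {
  int c = 0;
  for (; x; x >>= 1) c += (x & 1u);
  return c;
}

} // namespace

// [[Rcpp::export(name = ".tail_enum_cpp")]]
List tail_enum_cpp(IntegerVector margins, int n, int t_obs,
                   double epsilon = -1.0) {
  int k = margins.size();
  long S = 0;
  for (int j = 0; j < k; ++j) {
    if (margins[j] < 0 || margins[j] > n)
      stop("margins must lie in [0, n]");
    S += margins[j];
  }
  long w_max = S - t_obs;
  if (w_max < 0)
    stop("inconsistent table: T exceeds the sum of the margins");

  TailEnum e;
  e.k = k;
  e.n = n;
  e.w_max = w_max;
  e.eps = epsilon;
  // log-factorial table, cached across calls and grown on demand
  static std::vector<double> lfac_cache(1, 0.0);
  while ((int)lfac_cache.size() <= n)
    lfac_cache.push_back(lfac_cache.back() +
                         std::log((double)lfac_cache.size()));
  e.lfac.assign(lfac_cache.begin(), lfac_cache.begin() + n + 1);

  // co-occurring cells in decreasing |v|
  for (int sz = k; sz >= 2; --sz)
    for (unsigned m = 1; m < (1u << k); ++m)
      if (popcount_int(m) == sz) {
        std::vector<int> v;
        for (int j = 0; j < k; ++j)
          if (m & (1u << j)) v.push_back(j);
        e.members.push_back(v);
        e.csize.push_back(sz);
      }

  e.mar.assign(margins.begin(), margins.end());
  e.cst = 0.0;
  for (int j = 0; j < k; ++j)
    e.cst += e.lfac[margins[j]] + e.lfac[n - margins[j]];
  e.cst -= (double)(k - 1) * e.lfac[n];

  e.rec(0, w_max, 0.0, 0);

  return List::create(_["p_ge"] = e.p_ge, _["p_gt"] = e.p_gt,
                      _["complete"] = !e.stopped,
                      _["enumerated_tables"] = e.ntab);
}
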