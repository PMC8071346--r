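// Circular binary segmentation engine.
//
// The change statistic for an arc (i, j] of a length-n segment is the
// standardized difference between the arc mean and the mean of its
// complement,
//     T(i,j) = |C_j - C_i| / (sd * sqrt(k (n - k) / n)),  k = j - i,
// where C_i = S_i - (i/n) S_n are centered partial sums and sd is the
// within-segment standard deviation (constant over arcs, so T is a pure
// function of the partial sums).  A wrapped arc yields the same split as
// its complement, so enumerating 0 <= i < j <= n covers the circle.
//
// Exhaustive enumeration of arcs is O(n^2) per evaluation, far too slow
// inside a permutation test on genome-scale chromosomes.  The statistic
// is therefore the maximum over a restricted arc family: all arcs of
// length <= kshort (and, symmetrically, >= n - kshort), plus every arc
// whose two endpoints lie among the ncand smallest and ncand largest
// centered partial sums.  The same family is searched for the observed
// data and for every permutation replicate, so the permutation test is
// exact for this statistic.  Short arcs cover focal CNVs exhaustively;
// the extreme-partial-sum candidates catch long and intermediate shifts
// because a sustained shift drives the partial-sum walk to an extreme at
// each of its boundaries.  For segments with n <= 2 * kshort the family
// is the full arc set, so small instances are searched exhaustively.
//
// Split significance uses sequential early stopping: a split is rejected
// as soon as exceedances make p clearly above alpha, and accepted once
// zero exceedances make the exact binomial 97.5% upper bound on p fall
// below alpha.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Arc {
  double t;
  int i, j;  // split after i and after j (0-based cut positions)
};

static inline double arc_t(const std::vector<double>& C, int n, int i, int j,
                           double sd) {
  int k = j - i;
  double denom = sd * std::sqrt((double)k * (n - k) / n);
  return std::fabs(C[j] - C[i]) / denom;
}

static void scan_k_range(const std::vector<double>& C, int n, double sd,
                         int klo, int khi, Arc& best) {
  for (int k = klo; k <= khi; ++k) {
    double w = sd * std::sqrt((double)k * (n - k) / n);
    double dmax = 0.0;
    int imax = 0;
    for (int i = 0; i + k <= n; ++i) {
      double d = std::fabs(C[i + k] - C[i]);
      if (d > dmax) { dmax = d; imax = i; }
    }
    double t = dmax / w;
    if (t > best.t) { best.t = t; best.i = imax; best.j = imax + k; }
  }
}

static void scan_all_pairs(const std::vector<double>& C, int n, double sd,
                           int minw, Arc& best) {
  for (int i = 0; i <= n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int k = j - i;
      if (k < minw || k > n - minw) continue;
      double t = arc_t(C, n, i, j, sd);
      if (t > best.t) { best.t = t; best.i = i; best.j = j; }
    }
  }
}

static void scan_candidates(const std::vector<double>& C, int n, double sd,
                            int minw, int ncand, Arc& best,
                            std::vector<int>& ord, std::vector<int>& cand) {
  int m = n + 1;
  if (2 * ncand >= m) {  // few enough endpoints: search exhaustively
    scan_all_pairs(C, n, sd, minw, best);
    return;
  }
  ord.resize(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::partial_sort(ord.begin(), ord.begin() + ncand, ord.end(),
                    [&](int a, int b) { return C[a] < C[b]; });
  cand.assign(ord.begin(), ord.begin() + ncand);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::partial_sort(ord.begin(), ord.begin() + ncand, ord.end(),
                    [&](int a, int b) { return C[a] > C[b]; });
  cand.insert(cand.end(), ord.begin(), ord.begin() + ncand);
  int nc = (int)cand.size();
  for (int a = 0; a < nc; ++a) {
    for (int b = a + 1; b < nc; ++b) {
      int i = std::min(cand[a], cand[b]);
      int j = std::max(cand[a], cand[b]);
      int k = j - i;
      if (k < minw || k > n - minw) continue;
      double t = arc_t(C, n, i, j, sd);
      if (t > best.t) { best.t = t; best.i = i; best.j = j; }
    }
  }
}

// Maximum of the restricted-family statistic; identical search for
// observed data and permutation replicates.
static Arc max_arc(const std::vector<double>& C, int n, double sd, int minw,
                   int kshort, int ncand, std::vector<int>& ord,
                   std::vector<int>& cand) {
  Arc best = {0.0, 0, 0};
  if (n - minw < minw || sd <= 0.0) return best;
  int khi = std::min(kshort, n - minw);
  scan_k_range(C, n, sd, minw, khi, best);
  int klo = std::max(minw, n - kshort);
  if (klo > khi) scan_k_range(C, n, sd, klo, n - minw, best);
  scan_candidates(C, n, sd, minw, ncand, best, ord, cand);
  return best;
}

static void centered_psums(const std::vector<double>& x,
                           std::vector<double>& C) {
  int n = (int)x.size();
  C.resize(n + 1);
  C[0] = 0.0;
  for (int i = 0; i < n; ++i) C[i + 1] = C[i] + x[i];
  double Sn = C[n];
  for (int i = 1; i <= n; ++i) C[i] -= (double)i / n * Sn;
}

static double segment_sd(const std::vector<double>& x) {
  int n = (int)x.size();
  double m = 0.0;
  for (double v : x) m += v;
  m /= n;
  double ss = 0.0;
  for (double v : x) ss += (v - m) * (v - m);
  return std::sqrt(ss / n);
}

// Does any arc of the restricted family reach `thresh`?  Candidates are
// checked first (they usually carry the maximum), short arcs after, with
// early exit on the first exceedance.
static bool any_arc_exceeds(const std::vector<double>& C, int n, double sd,
                            int minw, int kshort, int ncand, double thresh,
                            std::vector<int>& ord, std::vector<int>& cand) {
  if (sd <= 0.0) return false;
  Arc best = {0.0, 0, 0};
  scan_candidates(C, n, sd, minw, ncand, best, ord, cand);
  if (best.t >= thresh) return true;
  int khi = std::min(kshort, n - minw);
  for (int k = minw; k <= khi; ++k) {
    double dthr = thresh * sd * std::sqrt((double)k * (n - k) / n);
    for (int i = 0; i + k <= n; ++i)
      if (std::fabs(C[i + k] - C[i]) >= dthr) return true;
  }
  int klo = std::max(minw, n - kshort);
  if (klo > khi) {
    for (int k = klo; k <= n - minw; ++k) {
      double dthr = thresh * sd * std::sqrt((double)k * (n - k) / n);
      for (int i = 0; i + k <= n; ++i)
        if (std::fabs(C[i + k] - C[i]) >= dthr) return true;
    }
  }
  return false;
}

// Permutation p-value with sequential early stopping.  Returns true if
// the split is accepted (p < alpha).
//
// For long segments an overwhelming statistic is accepted without
// permutations: a Bonferroni bound over the restricted arc family with
// Gaussian tails gives p <= N_arcs * erfc(t / sqrt(2)), conservative
// under approximate normality of bin values; it is required to fall
// below alpha / 10 to leave a wide safety margin, and borderline
// statistics always go through the permutation test.
static bool perm_accept(std::vector<double> x, double t_obs, double alpha,
                        int nperm, int minw, int kshort, int ncand) {
  int n = (int)x.size();
  if (n >= 100) {
    double n_arcs = 2.0 * kshort * n + 4.0 * ncand * ncand;
    double p_bound = n_arcs * std::erfc(t_obs / std::sqrt(2.0));
    if (p_bound < alpha / 10.0) return true;
  }
  int cr_full = (int)std::ceil(alpha * nperm);
  int m_accept = (int)std::ceil(std::log(0.025) / std::log(1.0 - alpha));
  if (m_accept > nperm) m_accept = nperm;
  // permutation draws are capped: when a split is still undecided after
  // this many replicates, the point estimate of p settles it (resolution
  // +/- 0.004 at the cap, enough for decisions at alpha = 0.01)
  int seq_cap = std::min(nperm, 3000);
  double thresh = t_obs * (1.0 - 1e-12);
  std::vector<double> C;
  std::vector<int> ord, cand;
  int cnt = 0;
  for (int p = 1; p <= seq_cap; ++p) {
    for (int a = n - 1; a > 0; --a) {
      int b = (int)(unif_rand() * (a + 1));
      if (b > a) b = a;
      std::swap(x[a], x[b]);
    }
    centered_psums(x, C);
    double sd = segment_sd(x);
    if (any_arc_exceeds(C, n, sd, minw, kshort, ncand, thresh, ord, cand))
      ++cnt;
    if (cnt >= cr_full) return false;
    // reject when the normal-approximation lower confidence bound on p
    // clears alpha
    if (cnt >= 5 && cnt - 2.0 * std::sqrt((double)cnt) > alpha * p)
      return false;
    if (cnt == 0 && p >= m_accept) return true;
  }
  return (double)(cnt + 1) / (seq_cap + 1) < alpha;
}

// [[Rcpp::export]]
List cpp_max_arc(NumericVector x, int min_width = 1, int kshort = 12,
                 int ncand = 50) {
  std::vector<double> xv(x.begin(), x.end());
  int n = (int)xv.size();
  std::vector<double> C;
  std::vector<int> ord, cand;
  centered_psums(xv, C);
  double sd = segment_sd(xv);
  if (sd <= 0.0)
    return List::create(_["t"] = 0.0, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER);
  Arc a = max_arc(C, n, sd, min_width, kshort, ncand, ord, cand);
  return List::create(_["t"] = a.t, _["i"] = a.i, _["j"] = a.j);
}

// [[Rcpp::export]]
IntegerVector cpp_cbs_changepoints(NumericVector x, double alpha = 0.01,
                                   int nperm = 10000, int min_width = 1,
                                   int kshort = 12, int ncand = 50) {
  int n_total = x.size();
  std::vector<int> breaks;
  std::vector<std::pair<int, int>> stack;  // half-open [lo, hi)
  stack.push_back({0, n_total});
  std::vector<double> seg, C;
  std::vector<int> ord, cand;
  const double sd_tol = 1e-10;
  while (!stack.empty()) {
    int lo = stack.back().first, hi = stack.back().second;
    stack.pop_back();
    int n = hi - lo;
    if (n < 2 || n < 2 * min_width) continue;
    seg.assign(x.begin() + lo, x.begin() + hi);
    double sd = segment_sd(seg);
    double scale = 0.0;
    for (double v : seg) scale = std::max(scale, std::fabs(v));
    if (sd <= sd_tol * std::max(1.0, scale)) continue;  // constant segment
    centered_psums(seg, C);
    Arc a = max_arc(C, n, sd, min_width, kshort, ncand, ord, cand);
    if (a.t <= 0.0) continue;
    if (!perm_accept(seg, a.t, alpha, nperm, min_width, kshort, ncand))
      continue;
    int c1 = lo + a.i, c2 = lo + a.j;  // cuts after these positions
    if (c1 > lo) { breaks.push_back(c1); stack.push_back({lo, c1}); }
    if (c2 > c1) stack.push_back({c1, c2});
    if (c2 < hi) { breaks.push_back(c2); stack.push_back({c2, hi}); }
  }
  std::sort(breaks.begin(), breaks.end());
  breaks.erase(std::unique(breaks.begin(), breaks.end()), breaks.end());
  return wrap(breaks);
}
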