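#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Circular binary segmentation internals.
//
// The arc statistic for a segment x[0..m-1] and boundary pair (i, j),
// 0 <= i < j <= m, compares the mean of the arc x[i..j-1] (length k = j - i)
// with the mean of its circular complement, scaled by the pooled
// within-group variance. Work is done on t^2 to avoid a sqrt per pair.
// A zero pooled variance with unequal means maps to +Inf so that noiseless
// change points are always accepted.

namespace {

struct ScanBest {
  double t2;
  int i, j;
};

inline double pair_t2(const double *S, double Stot, double Qtot,
                      int m, int i, int j) {
  const int k = j - i;
  const int nc = m - k;
  const double sumA = S[j] - S[i];
  const double meanA = sumA / k;
  const double meanC = (Stot - sumA) / nc;
  double ss = Qtot - k * meanA * meanA - nc * meanC * meanC;
  if (ss < 0) ss = 0;
  const double d = meanA - meanC;
  if (m <= 2 || ss <= 1e-10 * (Qtot + 1e-300)) {
    if (d == 0.0) return 0.0;
    return R_PosInf;
  }
  const double s2 = ss / (m - 2);
  return d * d / (s2 * (1.0 / k + 1.0 / nc));
}

inline void consider(const double *S, double Stot, double Qtot, int m,
                     int i, int j, int min_width, ScanBest &best) {
  const int k = j - i;
  if (k < min_width || m - k < min_width) return;
  if (i == 0 && j == m) return;
  const double t2 = pair_t2(S, Stot, Qtot, m, i, j);
  if (t2 > best.t2) {
    best.t2 = t2;
    best.i = i;
    best.j = j;
  }
}

// Max of the arc statistic over the scan family. For short segments the
// scan is exhaustive; for long ones it combines (a) all short arcs
// (length <= kmax, which by arc/complement symmetry also covers near-full
// arcs), (b) a coarse grid over boundary pairs, and (c) two local
// refinement passes around the running optimum. Both the observed value
// and every permutation replicate use the same family, so the permutation
// test is self-consistent.
//
// If stop_at > 0, scanning aborts as soon as the running max reaches it
// (used to test permutation replicates against the observed statistic).
ScanBest scan_max(const std::vector<double> &x, int min_width, int kmax,
                  int ngrid, int exhaustive_limit, double stop_at) {
  const int m = (int)x.size();
  ScanBest best;
  best.t2 = -1.0;
  best.i = -1;
  best.j = -1;

  std::vector<double> S(m + 1);
  S[0] = 0.0;
  double Qtot = 0.0;
  for (int t = 0; t < m; ++t) {
    S[t + 1] = S[t] + x[t];
    Qtot += x[t] * x[t];
  }
  const double Stot = S[m];
  const double *Sp = S.data();

  if (m <= exhaustive_limit) {
    for (int i = 0; i <= m - 1; ++i) {
      for (int j = i + min_width; j <= m; ++j) {
        consider(Sp, Stot, Qtot, m, i, j, min_width, best);
      }
      if (stop_at > 0 && best.t2 >= stop_at) return best;
    }
    return best;
  }

  // (a) short arcs everywhere
  const int kcap = std::min(kmax, m - min_width);
  for (int k = min_width; k <= kcap; ++k) {
    for (int i = 0; i + k <= m; ++i) {
      consider(Sp, Stot, Qtot, m, i, i + k, min_width, best);
    }
    if (stop_at > 0 && best.t2 >= stop_at) return best;
  }

  // (b) coarse grid on boundary pairs
  int g = m / ngrid;
  if (g < 1) g = 1;
  for (int i = 0; i <= m; i += g) {
    for (int j = i + g; j <= m; j += g) {
      consider(Sp, Stot, Qtot, m, i, j, min_width, best);
    }
  }
  if (stop_at > 0 && best.t2 >= stop_at) return best;

  // (c) refinement around the optimum: coarse window, then unit step
  int steps[2];
  steps[0] = std::max(1, g / 8);
  steps[1] = 1;
  int radius = g;
  for (int pass = 0; pass < 2; ++pass) {
    const int st = steps[pass];
    const int ci = best.i, cj = best.j;
    const int ilo = std::max(0, ci - radius), ihi = std::min(m, ci + radius);
    const int jlo = std::max(0, cj - radius), jhi = std::min(m, cj + radius);
    for (int i = ilo; i <= ihi; i += st) {
      for (int j = std::max(jlo, i + min_width); j <= jhi; j += st) {
        consider(Sp, Stot, Qtot, m, i, j, min_width, best);
      }
    }
    radius = steps[0];
    if (stop_at > 0 && best.t2 >= stop_at) return best;
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".cbs_scan_max")]]
List cbs_scan_max(NumericVector x, int min_width, int kmax, int ngrid,
                  int exhaustive_limit) {
  std::vector<double> v(x.begin(), x.end());
  ScanBest b = scan_max(v, min_width, kmax, ngrid, exhaustive_limit, -1.0);
  const double stat = (b.t2 < 0) ? 0.0 : (std::isinf(b.t2) ? R_PosInf
                                                           : std::sqrt(b.t2));
  return List::create(_["stat"] = stat, _["i"] = b.i, _["j"] = b.j);
}

// Recursive CBS on a single profile. Split acceptance: the observed max
// statistic must rank above the (1 - alpha) fraction of permutation maxima,
// i.e. #{perm >= obs} <= floor(alpha * nperm). Permutation counting stops
// early in both directions: once a split can no longer be accepted, and
// (sequential early acceptance) once 50 replicates have produced no
// exceedance and no permutation maximum within 60% of the observed t^2 --
// far from the decision boundary the full replicate count adds nothing.
// Returns a matrix with columns start, end (1-based, inclusive) and mean.
// [[Rcpp::export(name = ".cbs_segment")]]
NumericMatrix cbs_segment(NumericVector x, double alpha, int nperm,
                          int min_width, int kmax, int ngrid,
                          int exhaustive_limit) {
  const int P = x.size();
  std::vector<std::pair<int, int> > todo, done;
  todo.push_back(std::make_pair(0, P - 1));
  const int limit = (int)std::floor(alpha * nperm);

  while (!todo.empty()) {
    const std::pair<int, int> seg = todo.back();
    todo.pop_back();
    const int a = seg.first, b = seg.second;
    const int m = b - a + 1;
    if (m < 2 * min_width) {
      done.push_back(seg);
      continue;
    }
    std::vector<double> v(x.begin() + a, x.begin() + b + 1);
    ScanBest obs = scan_max(v, min_width, kmax, ngrid, exhaustive_limit, -1.0);
    if (!(obs.t2 > 0)) {
      done.push_back(seg);
      continue;
    }
    int exceed = 0;
    double perm_best = 0.0;
    std::vector<double> w(v);
    for (int p = 0; p < nperm && exceed <= limit; ++p) {
      for (int t = m - 1; t > 0; --t) {
        const int r = (int)(unif_rand() * (t + 1));
        std::swap(w[t], w[r <= t ? r : t]);
      }
      ScanBest pb = scan_max(w, min_width, kmax, ngrid, exhaustive_limit,
                             obs.t2);
      if (pb.t2 >= obs.t2) ++exceed;
      if (pb.t2 > perm_best) perm_best = pb.t2;
      if (p + 1 >= 50 && exceed == 0 && perm_best <= 0.6 * obs.t2) break;
    }
    if (exceed > limit) {
      done.push_back(seg);
      continue;
    }
    // accepted: split into up to three children
    const int i = obs.i, j = obs.j;  // local boundaries, arc (i, j]
    if (i > 0) todo.push_back(std::make_pair(a, a + i - 1));
    todo.push_back(std::make_pair(a + i, a + j - 1));
    if (j < m) todo.push_back(std::make_pair(a + j, b));
  }

  std::sort(done.begin(), done.end());
  NumericMatrix out(done.size(), 3);
  for (size_t r = 0; r < done.size(); ++r) {
    const int a = done[r].first, b = done[r].second;
    double s = 0.0;
    for (int t = a; t <= b; ++t) s += x[t];
    out(r, 0) = a + 1;
    out(r, 1) = b + 1;
    out(r, 2) = s / (b - a + 1);
  }
  return out;
}

// Medians of nreps samples of size n drawn uniformly with replacement
// from pool. Uses the interpolated (mean-of-two-middles) median.
// [[Rcpp::export(name = ".resample_medians")]]
NumericVector resample_medians(NumericVector pool, int n, int nreps) {
  const int psize = pool.size();
  if (psize < 1) stop("empty pool");
  if (n < 1) stop("n must be positive");
  NumericVector out(nreps);
  std::vector<double> buf(n);
  for (int r = 0; r < nreps; ++r) {
    for (int t = 0; t < n; ++t) {
      int idx = (int)(unif_rand() * psize);
      if (idx >= psize) idx = psize - 1;
      buf[t] = pool[idx];
    }
    std::sort(buf.begin(), buf.end());
    out[r] = (n % 2 == 1) ? buf[n / 2]
                          : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
  }
  return out;
}
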