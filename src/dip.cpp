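// Hartigan-style dip statistic of unimodality.
//
// The dip of an empirical CDF F_n is the smallest band half-width d such
// that some CDF G, convex to the left of a mode m and concave to the right
// of it (a jump is allowed only at the mode), stays within d of F_n
// everywhere. Splitting at the mode, each side is a feasibility problem
// for a convex (resp. concave) sequence between the +/- d shifted corner
// staircases of F_n, which has a closed form: half the maximal deviation
// between one corner staircase and the convex hull of the opposite one.
// Crucially, the fitted flank must extend all the way to the mode: when m
// lies inside a gap between knots, the hull on each side gains a virtual
// corner point at (m, F(gap)) — without it, a steeply rising convex flank
// could illegally flatten across a wide plateau, and the dip of two
// well-separated clusters would be underestimated. The left requirement
// is nondecreasing and the right one nonincreasing in m, so the best mode
// position within a gap is found by bisection; gaps whose virtual-free
// lower bound already exceeds the current best are pruned.
//
// Complexity O(K^2) in the number K of distinct values plus O(K) bisection
// searches for the surviving gaps. The Monte Carlo null sampler reuses
// R's RNG stream so p-values are seed-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct P2 { double x, y; };

inline double cross(const P2& o, const P2& a, const P2& b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

struct Knots {
  std::vector<double> t;   // distinct sorted values, size K
  std::vector<double> cl;  // ECDF left limit at t[i]
  std::vector<double> cu;  // ECDF value at t[i]
};

void compress(const std::vector<double>& xs, Knots& kn) {
  const int n = static_cast<int>(xs.size());
  kn.t.clear(); kn.cl.clear(); kn.cu.clear();
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    kn.t.push_back(xs[i]);
    kn.cl.push_back(static_cast<double>(i) / n);
    kn.cu.push_back(static_cast<double>(j) / n);
    i = j;
  }
}

// interpolate a polyline (vertices in increasing x) at query x
inline double polyval(const std::vector<P2>& h, int lo, int hi, double x) {
  // vertices h[lo..hi]; x within [h[lo].x, h[hi].x]
  int a = lo;
  while (a < hi && h[a + 1].x <= x) ++a;
  if (a == hi) return h[a].y;
  const P2& p = h[a]; const P2& q = h[a + 1];
  return p.y + (q.y - p.y) * ((x - p.x) / (q.x - p.x));
}

// Max deviation of the upper corners (t_j, cu_j), j in [0, k) above the
// polyline formed by hull[0..top] (lower convex hull) optionally extended
// by a virtual last vertex v. devExcl leaves out j = k-1.
void left_dev(const Knots& kn, const std::vector<P2>& hull, int top,
              const P2* v, int k, double& devAll, double& devExcl) {
  devAll = devExcl = 0.0;
  int seg = 0;
  const int nseg = top + (v ? 1 : 0);   // index of last vertex
  for (int j = 0; j < k; ++j) {
    double x = kn.t[j];
    while (seg < nseg) {
      double nx = (seg + 1 <= top) ? hull[seg + 1].x : v->x;
      if (nx <= x) ++seg; else break;
    }
    P2 p = (seg <= top) ? hull[seg] : *v;
    double y;
    if (seg == nseg) {
      y = p.y;
    } else {
      P2 q = (seg + 1 <= top) ? hull[seg + 1] : *v;
      y = p.y + (q.y - p.y) * ((x - p.x) / (q.x - p.x));
    }
    double dev = kn.cu[j] - y;
    if (dev > devAll) devAll = dev;
    if (j < k - 1 && dev > devExcl) devExcl = dev;
  }
}

// Max deviation of the suffix upper-corner hull (vertices ascending in
// hull[lo..hi], optionally preceded by virtual vertex v) above the lower
// corners (t_i, cl_i), i in [j0, K). devExcl leaves out i = j0.
void right_dev(const Knots& kn, const std::vector<P2>& hull, int lo, int hi,
               const P2* v, int j0, double& devAll, double& devExcl) {
  devAll = devExcl = 0.0;
  const int K = static_cast<int>(kn.t.size());
  int seg = v ? -1 : lo;   // current left vertex (-1 = virtual)
  for (int i = j0; i < K; ++i) {
    double x = kn.t[i];
    while (true) {
      int nxt = (seg < 0) ? lo : seg + 1;
      if (nxt <= hi && hull[nxt].x <= x) seg = nxt; else break;
    }
    P2 p = (seg < 0) ? *v : hull[seg];
    double y;
    int nxt = (seg < 0) ? lo : seg + 1;
    if (nxt > hi) {
      y = p.y;
    } else {
      P2 q = hull[nxt];
      y = p.y + (q.y - p.y) * ((x - p.x) / (q.x - p.x));
    }
    double dev = y - kn.cl[i];
    if (dev > devAll) devAll = dev;
    if (i > j0 && dev > devExcl) devExcl = dev;
  }
}

double dip_of_sorted(const std::vector<double>& xs) {
  if (xs.size() < 2) return 0.0;
  Knots kn;
  compress(xs, kn);
  const int K = static_cast<int>(kn.t.size());
  if (K == 1) return 0.0;

  // ---- suffix pass: dR[j] (all deviations), dRm[j] (mode at knot j) ----
  std::vector<double> dR(K + 1, 0.0), dRm(K + 1, 0.0);
  {
    std::vector<P2> uh;   // upper hull, built right-to-left (descending x)
    uh.reserve(K);
    for (int j = K - 1; j >= 0; --j) {
      P2 np = {kn.t[j], kn.cu[j]};
      while (uh.size() >= 2 &&
             cross(uh[uh.size() - 2], uh[uh.size() - 1], np) <= 0.0)
        uh.pop_back();
      uh.push_back(np);
      // vertices ascending = reverse of uh; evaluate by walking a copy
      std::vector<P2> asc(uh.rbegin(), uh.rend());
      double dA, dE;
      right_dev(kn, asc, 0, static_cast<int>(asc.size()) - 1, nullptr, j,
                dA, dE);
      dR[j] = dA / 2.0;
      dRm[j] = dE / 2.0;
    }
  }

  // ---- prefix pass with gap searches ----
  std::vector<double> dL(K + 1, 0.0), dLk(K + 1, 0.0);
  double best = 1.0;
  // boundary gaps (mode outside the data)
  best = std::min(best, dR[0]);

  std::vector<P2> lh;   // lower hull of (t_i, cl_i), ascending
  lh.reserve(K);
  std::vector<P2> suf;  // scratch: suffix upper hull, ascending
  for (int k = 1; k <= K; ++k) {
    P2 np = {kn.t[k - 1], kn.cl[k - 1]};
    while (lh.size() >= 2 &&
           cross(lh[lh.size() - 2], lh[lh.size() - 1], np) <= 0.0)
      lh.pop_back();
    lh.push_back(np);
    double dA, dE;
    left_dev(kn, lh, static_cast<int>(lh.size()) - 1, nullptr, k, dA, dE);
    dL[k] = dA / 2.0;
    dLk[k] = dE / 2.0;
    // mode at knot k-1: left over knots 0..k-2 plus the virtual upper
    // corner at t_{k-1} (already a hull point), right from knot k-1
    best = std::min(best, std::max(dLk[k], dRm[k - 1]));
    if (k == K) {
      best = std::min(best, dL[K]);   // mode after all data
      break;
    }
    // interior gap (t_{k-1}, t_k): prune with the virtual-free lower bound
    if (std::max(dL[k], dR[k]) >= best) continue;

    // rebuild the suffix hull for knots k..K-1, ascending
    suf.clear();
    for (int i = k; i < K; ++i) {
      P2 q = {kn.t[i], kn.cu[i]};
      while (suf.size() >= 2 &&
             cross(suf[suf.size() - 2], suf[suf.size() - 1], q) >= 0.0)
        suf.pop_back();
      suf.push_back(q);
    }
    const double ck = kn.cu[k - 1];
    const double mlo = kn.t[k - 1], mhi = kn.t[k];
    auto evalL = [&](double m) {
      P2 v = {m, ck};
      int top = static_cast<int>(lh.size()) - 1;
      while (top >= 1 && cross(lh[top - 1], lh[top], v) <= 0.0) --top;
      double a, e;
      left_dev(kn, lh, top, &v, k, a, e);
      return a / 2.0;
    };
    auto evalR = [&](double m) {
      P2 v = {m, ck};
      int lo = 0;
      int hi = static_cast<int>(suf.size()) - 1;
      while (lo + 1 <= hi && cross(v, suf[lo], suf[lo + 1]) >= 0.0) ++lo;
      double a, e;
      right_dev(kn, suf, lo, hi, &v, k, a, e);
      return a / 2.0;
    };
    double eps = 1e-9 * (mhi - mlo);
    double a = mlo + eps, b2 = mhi - eps;
    // the gap's optimum is at least max(L(a), R(b)): L rises with m and R
    // falls, so these endpoint values bound every max(L, R) from below
    double La = evalL(a), Rb = evalR(b2);
    if (std::max(La, Rb) >= best) continue;
    double cand = std::min(std::max(La, evalR(a)),
                           std::max(evalL(b2), Rb));
    // left requirement rises with m, right requirement falls: bisect the
    // crossing of the two monotone curves
    for (int it = 0; it < 48 && b2 - a > 0; ++it) {
      double mid = 0.5 * (a + b2);
      double L = evalL(mid), R = evalR(mid);
      cand = std::min(cand, std::max(L, R));
      if (L <= R) a = mid; else b2 = mid;
    }
    best = std::min(best, cand);
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
double dip_statistic_sorted(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  if (!std::is_sorted(xs.begin(), xs.end()))
    stop("input must be sorted");
  return dip_of_sorted(xs);
}

namespace {

// Solve (A + ridge I) w = rhs for small symmetric positive definite A via
// Cholesky; A is modified in place.
bool chol_solve(std::vector<double>& A, std::vector<double>& w, int d) {
  for (int j = 0; j < d; ++j) {
    double s = A[j * d + j];
    for (int k = 0; k < j; ++k) s -= A[j * d + k] * A[j * d + k];
    if (s <= 0) return false;
    A[j * d + j] = std::sqrt(s);
    for (int i = j + 1; i < d; ++i) {
      double v = A[i * d + j];
      for (int k = 0; k < j; ++k) v -= A[i * d + k] * A[j * d + k];
      A[i * d + j] = v / A[j * d + j];
    }
  }
  // forward then backward substitution
  for (int i = 0; i < d; ++i) {
    double v = w[i];
    for (int k = 0; k < i; ++k) v -= A[i * d + k] * w[k];
    w[i] = v / A[i * d + i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double v = w[i];
    for (int k = i + 1; k < d; ++k) v -= A[k * d + i] * w[k];
    w[i] = v / A[i * d + i];
  }
  return true;
}

}  // namespace

// Null distribution for the discriminant-projection dip: each replicate
// draws n iid standard Gaussian points in d dimensions, splits them in two
// by 2-means (a stand-in for the dendrogram's binary split, selecting a
// spatially coherent partition the same way), projects onto the
// ridge-regularized two-class discriminant direction, and returns the dip
// of the projections. This reproduces the selection effect that makes
// projections of even unimodal data look separated, which the plain
// uniform dip null ignores.
// [[Rcpp::export]]
NumericVector dip_null_projsplit_mc(int n, int d, int b) {
  if (n < 4 || d < 1 || b < 1) stop("invalid n, d or b");
  NumericVector out(b);
  std::vector<double> X(n * d), w(d), m1(d), m2(d), sw(d * d);
  std::vector<int> lab(n);
  std::vector<double> proj(n);
  for (int rep = 0; rep < b; ++rep) {
    { NumericVector g = rnorm(n * d);
      std::copy(g.begin(), g.end(), X.begin()); }
    // 2-means, centers seeded from two random distinct points
    int c1 = static_cast<int>(R::unif_rand() * n);
    int c2 = static_cast<int>(R::unif_rand() * (n - 1));
    if (c2 >= c1) ++c2;
    for (int j = 0; j < d; ++j) { m1[j] = X[c1 * d + j]; m2[j] = X[c2 * d + j]; }
    int n1 = 0, n2 = 0;
    for (int it = 0; it < 10; ++it) {
      n1 = n2 = 0;
      for (int i = 0; i < n; ++i) {
        double d1 = 0, d2 = 0;
        for (int j = 0; j < d; ++j) {
          double a = X[i * d + j] - m1[j]; d1 += a * a;
          double bb = X[i * d + j] - m2[j]; d2 += bb * bb;
        }
        lab[i] = (d1 <= d2) ? 0 : 1;
        if (lab[i] == 0) ++n1; else ++n2;
      }
      if (n1 == 0 || n2 == 0) { lab[0] = (n1 == 0) ? 0 : 1; n1 = std::max(n1, 1); n2 = std::max(n2, 1); }
      std::fill(m1.begin(), m1.end(), 0.0);
      std::fill(m2.begin(), m2.end(), 0.0);
      n1 = n2 = 0;
      for (int i = 0; i < n; ++i) {
        double* m = lab[i] == 0 ? m1.data() : m2.data();
        for (int j = 0; j < d; ++j) m[j] += X[i * d + j];
        if (lab[i] == 0) ++n1; else ++n2;
      }
      if (n1 == 0 || n2 == 0) break;
      for (int j = 0; j < d; ++j) { m1[j] /= n1; m2[j] /= n2; }
    }
    if (n1 < 2 || n2 < 2) {
      // degenerate 2-means split: separate along the first coordinate
      std::vector<double> c0(n);
      for (int i = 0; i < n; ++i) c0[i] = X[i * d];
      std::nth_element(c0.begin(), c0.begin() + n / 2, c0.end());
      double med = c0[n / 2];
      n1 = n2 = 0;
      std::fill(m1.begin(), m1.end(), 0.0);
      std::fill(m2.begin(), m2.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        lab[i] = (X[i * d] < med) ? 0 : 1;
        double* m = lab[i] == 0 ? m1.data() : m2.data();
        for (int j = 0; j < d; ++j) m[j] += X[i * d + j];
        if (lab[i] == 0) ++n1; else ++n2;
      }
      if (n1 < 2 || n2 < 2) { out[rep] = 0; continue; }
      for (int j = 0; j < d; ++j) { m1[j] /= n1; m2[j] /= n2; }
    }
    // pooled within-class scatter + trace-scaled ridge
    std::fill(sw.begin(), sw.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double* m = lab[i] == 0 ? m1.data() : m2.data();
      for (int j = 0; j < d; ++j) {
        double aj = X[i * d + j] - m[j];
        for (int k = 0; k <= j; ++k)
          sw[j * d + k] += aj * (X[i * d + k] - m[k]);
      }
    }
    double tr = 0;
    for (int j = 0; j < d; ++j) { tr += sw[j * d + j]; }
    double ridge = 1e-6 * tr / d;
    if (ridge <= 0) ridge = 1e-6;
    for (int j = 0; j < d; ++j) {
      sw[j * d + j] += ridge;
      for (int k = 0; k < j; ++k) sw[k * d + j] = sw[j * d + k];
    }
    for (int j = 0; j < d; ++j) w[j] = m1[j] - m2[j];
    if (!chol_solve(sw, w, d)) {
      for (int j = 0; j < d; ++j) w[j] = m1[j] - m2[j];
    }
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int j = 0; j < d; ++j) s += X[i * d + j] * w[j];
      proj[i] = s;
    }
    std::sort(proj.begin(), proj.end());
    out[rep] = dip_of_sorted(proj);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector dip_null_mc(int n, int b) {
  if (n < 2 || b < 1) stop("invalid n or b");
  NumericVector out(b);
  std::vector<double> xs(n);
  for (int i = 0; i < b; ++i) {
    NumericVector u = runif(n);
    std::copy(u.begin(), u.end(), xs.begin());
    std::sort(xs.begin(), xs.end());
    out[i] = dip_of_sorted(xs);
  }
  return out;
}
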