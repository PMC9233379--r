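// Compiled kernels for the point-pattern and LISA analyses.
//
// Edge correction for Ripley's K uses the isotropic (circumference
// fraction) weight: closed form for axis-aligned rectangular windows,
// exact circle/edge arc intersection for arbitrary simple polygons.
// All randomness draws from R's RNG so seeding happens on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------- geometry

// crossing-number point-in-polygon; 1 inside, 0 boundary, -1 outside
static int pip(double px, double py, const NumericMatrix &ring, double eps) {
  int n = ring.nrow();
  bool inside = false, onbd = false;
  for (int e = 0; e < n; ++e) {
    double ax = ring(e, 0), ay = ring(e, 1);
    int f = (e + 1) % n;
    double bx = ring(f, 0), by = ring(f, 1);
    // distance to segment
    double dx = bx - ax, dy = by - ay;
    double l2 = dx * dx + dy * dy;
    double t = l2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / l2 : 0.0;
    t = std::min(1.0, std::max(0.0, t));
    double qx = ax + t * dx - px, qy = ay + t * dy - py;
    if (qx * qx + qy * qy <= eps * eps) onbd = true;
    if ((ay > py) != (by > py)) {
      double xin = ax + (py - ay) * (bx - ax) / (by - ay);
      if (px < xin) inside = !inside;
    }
  }
  if (onbd) return 0;
  return inside ? 1 : -1;
}

static double ring_eps(const NumericMatrix &ring) {
  double mx = 1.0;
  for (int i = 0; i < ring.nrow(); ++i) {
    mx = std::max(mx, std::fabs(ring(i, 0)));
    mx = std::max(mx, std::fabs(ring(i, 1)));
  }
  return 1e-9 * mx;
}

// fraction of the circle (cx, cy, r) inside an axis-aligned rectangle;
// valid while the circle never reaches two opposite edges at once, which
// holds for the radius grids used here (<= 1/4 of the short extent)
static double weight_rect(double cx, double cy, double r,
                          double x0, double y0, double x1, double y1) {
  double d[4] = {cx - x0, x1 - cx, cy - y0, y1 - cy}; // L R B T
  double alpha[4];
  double aout = 0.0;
  for (int e = 0; e < 4; ++e) {
    if (d[e] < r) {
      double c = std::max(d[e], 0.0) / r;
      alpha[e] = 2.0 * std::acos(c);
      aout += alpha[e];
    } else {
      alpha[e] = 0.0;
    }
  }
  static const int c1[4] = {0, 1, 1, 0}; // (L,B) (R,B) (R,T) (L,T)
  static const int c2[4] = {2, 2, 3, 3};
  for (int c = 0; c < 4; ++c) {
    double dc = std::hypot(d[c1[c]], d[c2[c]]);
    if (dc < r) aout -= (alpha[c1[c]] / 2.0 + alpha[c2[c]] / 2.0 - M_PI / 2.0);
  }
  double w = 1.0 - aout / TWO_PI;
  return std::max(w, 1e-12);
}

// fraction of the circle (cx, cy, r) inside a simple polygon: exact arc
// intersection angles with every edge, then midpoint classification
static double weight_poly(double cx, double cy, double r,
                          const NumericMatrix &ring, double eps) {
  int n = ring.nrow();
  std::vector<double> angs;
  angs.reserve(2 * n + 2);
  angs.push_back(0.0);
  for (int e = 0; e < n; ++e) {
    double ax = ring(e, 0), ay = ring(e, 1);
    int f = (e + 1) % n;
    double bx = ring(f, 0), by = ring(f, 1);
    double ex = bx - ax, ey = by - ay;
    double fx = ax - cx, fy = ay - cy;
    double A = ex * ex + ey * ey;
    if (A == 0.0) continue;
    double B = 2.0 * (fx * ex + fy * ey);
    double C = fx * fx + fy * fy - r * r;
    double disc = B * B - 4.0 * A * C;
    if (disc <= 0.0) continue;
    double sq = std::sqrt(disc);
    for (int s = 0; s < 2; ++s) {
      double t = (s == 0 ? (-B - sq) : (-B + sq)) / (2.0 * A);
      if (t >= 0.0 && t <= 1.0) {
        double th = std::atan2(fy + t * ey, fx + t * ex);
        if (th < 0) th += TWO_PI;
        angs.push_back(th);
      }
    }
  }
  std::sort(angs.begin(), angs.end());
  angs.push_back(angs.front() + TWO_PI);
  double in_len = 0.0;
  for (size_t a = 0; a + 1 < angs.size(); ++a) {
    double lo = angs[a], hi = angs[a + 1];
    if (hi - lo <= 0.0) continue;
    double mid = (lo + hi) / 2.0;
    double px = cx + r * std::cos(mid), py = cy + r * std::sin(mid);
    if (pip(px, py, ring, eps) >= 0) in_len += hi - lo;
  }
  return std::max(in_len / TWO_PI, 1e-12);
}

// [[Rcpp::export]]
double cpp_edge_weight_rect(double cx, double cy, double r,
                            double x0, double y0, double x1, double y1) {
  return weight_rect(cx, cy, r, x0, y0, x1, y1);
}

// [[Rcpp::export]]
double cpp_edge_weight_poly(double cx, double cy, double r,
                            NumericMatrix ring) {
  return weight_poly(cx, cy, r, ring, ring_eps(ring));
}

// ---------------------------------------------------------------- Ripley K

// accumulate edge-corrected pair contributions into radius buckets, then
// cumulative-sum: K(t) = (A / N^2) * sum over ordered pairs with d < t.
// bdist[i] is the distance from point i to the window boundary: circles
// with r <= bdist are entirely interior, so their weight is 1 and the
// trigonometric correction is skipped.
template <typename W>
static void k_core(const std::vector<double> &x, const std::vector<double> &y,
                   const NumericVector &radii, double area,
                   const std::vector<double> &bdist, W wfun, double *out) {
  int n = (int)x.size();
  int nr = radii.size();
  double tmax = radii[nr - 1];
  double tmax2 = tmax * tmax;
  std::vector<double> bucket(nr, 0.0);
  // uniform grids (the default) admit a direct bucket index
  double step = radii[0];
  bool uniform = step > 0.0;
  for (int m = 1; m < nr && uniform; ++m)
    if (std::fabs(radii[m] - (m + 1) * step) > 1e-9 * tmax) uniform = false;
  // x-sorted sweep: only pairs with |dx| < tmax are examined
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> sx(n), sy(n), sb(n);
  for (int i = 0; i < n; ++i) {
    sx[i] = x[ord[i]]; sy[i] = y[ord[i]]; sb[i] = bdist[ord[i]];
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n && sx[j] - sx[i] < tmax; ++j) {
      double dx = sx[i] - sx[j], dy = sy[i] - sy[j];
      double d2 = dx * dx + dy * dy;
      if (d2 >= tmax2) continue;
      double d = std::sqrt(d2);
      int idx;
      if (uniform) {
        idx = (int)(d / step);
        if (idx < nr && radii[idx] <= d) ++idx;  // strict d < t
      } else {
        idx = (int)(std::upper_bound(radii.begin(), radii.end(), d) -
                    radii.begin());
      }
      if (idx >= nr) continue;
      double wi = d <= sb[i] ? 1.0 : wfun(sx[i], sy[i], d);
      double wj = d <= sb[j] ? 1.0 : wfun(sx[j], sy[j], d);
      bucket[idx] += 1.0 / wi + 1.0 / wj;
    }
  }
  double acc = 0.0;
  double scale = area / ((double)n * (double)n);
  for (int m = 0; m < nr; ++m) {
    acc += bucket[m];
    out[m] = scale * acc;
  }
}

static double border_dist_rect(double px, double py, double x0, double y0,
                               double x1, double y1) {
  return std::min(std::min(px - x0, x1 - px), std::min(py - y0, y1 - py));
}

static double border_dist_poly(double px, double py,
                               const NumericMatrix &ring) {
  int n = ring.nrow();
  double best = R_PosInf;
  for (int e = 0; e < n; ++e) {
    double ax = ring(e, 0), ay = ring(e, 1);
    int f = (e + 1) % n;
    double bx = ring(f, 0), by = ring(f, 1);
    double dx = bx - ax, dy = by - ay;
    double l2 = dx * dx + dy * dy;
    double t = l2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / l2 : 0.0;
    t = std::min(1.0, std::max(0.0, t));
    double qx = ax + t * dx - px, qy = ay + t * dy - py;
    best = std::min(best, qx * qx + qy * qy);
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
NumericVector cpp_k_rect(NumericVector x, NumericVector y,
                         double x0, double y0, double x1, double y1,
                         NumericVector radii) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double area = (x1 - x0) * (y1 - y0);
  std::vector<double> bd(xv.size());
  for (size_t i = 0; i < xv.size(); ++i)
    bd[i] = border_dist_rect(xv[i], yv[i], x0, y0, x1, y1);
  NumericVector out(radii.size());
  k_core(xv, yv, radii, area, bd,
         [&](double cx, double cy, double r) {
           return weight_rect(cx, cy, r, x0, y0, x1, y1);
         },
         REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_k_poly(NumericVector x, NumericVector y, NumericMatrix ring,
                         double area, NumericVector radii) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double eps = ring_eps(ring);
  std::vector<double> bd(xv.size());
  for (size_t i = 0; i < xv.size(); ++i)
    bd[i] = border_dist_poly(xv[i], yv[i], ring);
  NumericVector out(radii.size());
  k_core(xv, yv, radii, area, bd,
         [&](double cx, double cy, double r) {
           return weight_poly(cx, cy, r, ring, eps);
         },
         REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_csr_k_rect(int n, double x0, double y0, double x1, double y1,
                             NumericVector radii, int nsims) {
  NumericMatrix out(nsims, radii.size());
  double area = (x1 - x0) * (y1 - y0);
  std::vector<double> xv(n), yv(n), bd(n), krow(radii.size());
  for (int s = 0; s < nsims; ++s) {
    for (int i = 0; i < n; ++i) {
      xv[i] = x0 + unif_rand() * (x1 - x0);
      yv[i] = y0 + unif_rand() * (y1 - y0);
      bd[i] = border_dist_rect(xv[i], yv[i], x0, y0, x1, y1);
    }
    k_core(xv, yv, radii, area, bd,
           [&](double cx, double cy, double r) {
             return weight_rect(cx, cy, r, x0, y0, x1, y1);
           },
           krow.data());
    for (int m = 0; m < (int)krow.size(); ++m) out(s, m) = krow[m];
    if (s % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_csr_k_poly(int n, NumericMatrix ring, double area,
                             NumericVector radii, int nsims) {
  NumericMatrix out(nsims, radii.size());
  double eps = ring_eps(ring);
  double bx0 = ring(0, 0), bx1 = ring(0, 0), by0 = ring(0, 1), by1 = ring(0, 1);
  for (int i = 0; i < ring.nrow(); ++i) {
    bx0 = std::min(bx0, ring(i, 0)); bx1 = std::max(bx1, ring(i, 0));
    by0 = std::min(by0, ring(i, 1)); by1 = std::max(by1, ring(i, 1));
  }
  std::vector<double> xv(n), yv(n), bd(n), krow(radii.size());
  for (int s = 0; s < nsims; ++s) {
    for (int i = 0; i < n; ++i) {
      double px, py;
      do {
        px = bx0 + unif_rand() * (bx1 - bx0);
        py = by0 + unif_rand() * (by1 - by0);
      } while (pip(px, py, ring, eps) < 0);
      xv[i] = px; yv[i] = py;
      bd[i] = border_dist_poly(px, py, ring);
    }
    k_core(xv, yv, radii, area, bd,
           [&](double cx, double cy, double r) {
             return weight_poly(cx, cy, r, ring, eps);
           },
           krow.data());
    for (int m = 0; m < (int)krow.size(); ++m) out(s, m) = krow[m];
    if (s % 10 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ------------------------------------------------------------------- LISA

// conditional permutation pseudo p-values for local Moran's I: unit i's
// value is held fixed, its neighbors' deviations are resampled without
// replacement from the remaining n-1 deviations; the count is one-sided
// in the direction of the observed statistic
// [[Rcpp::export]]
NumericVector cpp_perm_pvalues(NumericVector z, double m2, List nbs, List wts,
                               int nperm) {
  int n = z.size();
  NumericVector p(n, NA_REAL);
  std::vector<double> zo(n - 1);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = nbs[i];
    NumericVector w = wts[i];
    int k = nb.size();
    if (k == 0) continue; // island: no pseudo p
    double lag = 0.0;
    for (int a = 0; a < k; ++a) lag += w[a] * z[nb[a] - 1];
    double zi = z[i];
    double iobs = zi / m2 * lag;
    int m = 0;
    for (int j = 0; j < n; ++j) if (j != i) zo[m++] = z[j];
    std::vector<int> pick(k);
    int cnt = 0;
    for (int perm = 0; perm < nperm; ++perm) {
      for (int a = 0; a < k; ++a) {
        int idx;
        bool ok;
        do {
          idx = (int)(unif_rand() * m);
          if (idx == m) idx = m - 1;
          ok = true;
          for (int b = 0; b < a; ++b)
            if (pick[b] == idx) { ok = false; break; }
        } while (!ok);
        pick[a] = idx;
      }
      double lg = 0.0;
      for (int a = 0; a < k; ++a) lg += w[a] * zo[pick[a]];
      double ist = zi / m2 * lg;
      if (iobs >= 0.0) {
        if (ist >= iobs) ++cnt;
      } else {
        if (ist <= iobs) ++cnt;
      }
    }
    p[i] = (cnt + 1.0) / (nperm + 1.0);
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return p;
}
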