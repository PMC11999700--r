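#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spatial neighbour queries for planar point patterns. Coordinates are in
// micrometres; ties in distance are broken by point index so that results are
// reproducible and match the sort-based oracles in the test suite.

namespace {

struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins;

  Grid(const NumericVector &x, const NumericVector &y, double target_per_cell) {
    int n = x.size();
    double xmin = *std::min_element(x.begin(), x.end());
    double xmax = *std::max_element(x.begin(), x.end());
    double ymin = *std::min_element(y.begin(), y.end());
    double ymax = *std::max_element(y.begin(), y.end());
    double sx = xmax - xmin, sy = ymax - ymin;
    double span = std::max(std::max(sx, sy), 1e-9);
    double area = std::max(sx, 1e-9) * std::max(sy, 1e-9);
    // 2-D estimate, with a 1-D floor so collinear inputs still give a few
    // points per occupied bin rather than a near-infinite bin count
    cell = std::max(std::sqrt(area * target_per_cell / std::max(n, 1)),
                    span * target_per_cell / std::max(n, 1));
    if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;
    x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::floor(sx / cell) + 1);
    ny = std::max(1, (int)std::floor(sy / cell) + 1);
    // cap the grid so pathological aspect ratios cannot blow up memory
    while ((double)nx * ny > 4.0 * n + 64) {
      cell *= 2;
      nx = std::max(1, (int)std::floor(sx / cell) + 1);
      ny = std::max(1, (int)std::floor(sy / cell) + 1);
    }
    bins.assign((size_t)nx * ny, {});
    for (int i = 0; i < n; ++i) bins[idx(x[i], y[i])].push_back(i);
  }
  int clampx(int cx) const { return std::min(std::max(cx, 0), nx - 1); }
  int clampy(int cy) const { return std::min(std::max(cy, 0), ny - 1); }
  size_t idx(double px, double py) const {
    int cx = clampx((int)std::floor((px - x0) / cell));
    int cy = clampy((int)std::floor((py - y0) / cell));
    return (size_t)cy * nx + cx;
  }
};

typedef std::pair<double, int> DI; // (squared distance, index)

inline bool di_less(const DI &a, const DI &b) {
  if (a.first != b.first) return a.first < b.first;
  return a.second < b.second;
}

// collect candidates in the square ring of Chebyshev radius r around (cx, cy)
void gather_ring(const Grid &g, int cx, int cy, int r, const NumericVector &rx,
                 const NumericVector &ry, double qx, double qy, int skip,
                 std::vector<DI> &out) {
  int xlo = cx - r, xhi = cx + r, ylo = cy - r, yhi = cy + r;
  for (int by = ylo; by <= yhi; ++by) {
    if (by < 0 || by >= g.ny) continue;
    for (int bx = xlo; bx <= xhi; ++bx) {
      if (bx < 0 || bx >= g.nx) continue;
      if (r > 0 && bx != xlo && bx != xhi && by != ylo && by != yhi) continue;
      const std::vector<int> &pts = g.bins[(size_t)by * g.nx + bx];
      for (int j : pts) {
        if (j == skip) continue;
        double dx = rx[j] - qx, dy = ry[j] - qy;
        out.push_back(DI(dx * dx + dy * dy, j));
      }
    }
  }
}

} // namespace

// k nearest neighbours among the points themselves (self excluded).
// Returns a 1-based n x k index matrix.
// [[Rcpp::export]]
IntegerMatrix knn2d_cpp(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  Grid g(x, y, 4.0);
  IntegerMatrix out(n, k);
  std::vector<DI> cand;
  int rmax = std::max(g.nx, g.ny);
  for (int i = 0; i < n; ++i) {
    cand.clear();
    int cx = g.clampx((int)std::floor((x[i] - g.x0) / g.cell));
    int cy = g.clampy((int)std::floor((y[i] - g.y0) / g.cell));
    for (int r = 0; r <= rmax; ++r) {
      gather_ring(g, cx, cy, r, x, y, x[i], y[i], i, cand);
      if ((int)cand.size() >= k) {
        std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end(), di_less);
        double dk = std::sqrt(cand[k - 1].first);
        // points in un-visited bins (Chebyshev bin distance > r) are at least
        // r * cell away from the query
        if (dk <= r * g.cell || r == rmax) break;
      }
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end(), di_less);
    for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;
  }
  return out;
}

// nearest reference point for each query point; returns 1-based index and
// distance. Reference and query sets may differ.
// [[Rcpp::export]]
List nn1_cpp(NumericVector rx, NumericVector ry, NumericVector qx, NumericVector qy) {
  int nr = rx.size(), nq = qx.size();
  if (nr < 1) stop("reference set is empty");
  Grid g(rx, ry, 4.0);
  IntegerVector idx(nq);
  NumericVector dist(nq);
  std::vector<DI> cand;
  int rmax = std::max(g.nx, g.ny) + 2;
  for (int i = 0; i < nq; ++i) {
    cand.clear();
    int cx = g.clampx((int)std::floor((qx[i] - g.x0) / g.cell));
    int cy = g.clampy((int)std::floor((qy[i] - g.y0) / g.cell));
    DI best(R_PosInf, -1);
    for (int r = 0; r <= rmax; ++r) {
      cand.clear();
      gather_ring(g, cx, cy, r, rx, ry, qx[i], qy[i], -1, cand);
      for (const DI &c : cand)
        if (di_less(c, best)) best = c;
      if (best.second >= 0 && (std::sqrt(best.first) <= r * g.cell || r == rmax)) break;
    }
    idx[i] = best.second + 1;
    dist[i] = std::sqrt(best.first);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// brute-force k nearest neighbours in feature space (rows of X), Euclidean or
// cosine distance; ties broken by row index. 1-based n x k matrix.
// [[Rcpp::export]]
IntegerMatrix knn_feature_cpp(NumericMatrix X, int k, bool cosine) {
  int n = X.nrow(), d = X.ncol();
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  NumericMatrix Z = clone(X);
  if (cosine) {
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int j = 0; j < d; ++j) s += Z(i, j) * Z(i, j);
      s = std::sqrt(s);
      if (s > 0)
        for (int j = 0; j < d; ++j) Z(i, j) /= s;
    }
  }
  IntegerMatrix out(n, k);
  std::vector<DI> cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double diff = Z(i, c) - Z(j, c);
        s += diff * diff;
      }
      cand[m++] = DI(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end(), di_less);
    for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;
  }
  return out;
}
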