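// Neighbour-search primitives for localization tables.
//
// Points are passed as matrices with columns x, y[, z] in nm. All spatial
// queries grid on x/y only (SMLM z extents are small relative to lateral
// extents) but measure full Euclidean distance. The optional toroidal metric
// wraps x and y on the region rectangle [x0, x0+Lx) x [y0, y0+Ly); it is
// intended for synthetic scenes, where it removes edge effects exactly.
//
// Everything here is deterministic; all randomness lives on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

struct Metric {
  bool toroidal;
  double Lx, Ly;
  double wrap(double d, double L) const {
    d = std::fabs(d);
    if (toroidal && d > 0.5 * L) d = L - d;
    return d;
  }
  double dist2(double x1, double y1, double z1, double x2, double y2,
               double z2) const {
    double dx = wrap(x1 - x2, Lx);
    double dy = wrap(y1 - y2, Ly);
    double dz = z1 - z2;
    return dx * dx + dy * dy + dz * dz;
  }
};

// Uniform cell grid over a point set (x/y only).
struct Grid {
  double x0, y0, hx, hy;
  int ncx, ncy;
  bool toroidal;
  std::vector<int> cell_start;   // size ncx*ncy+1
  std::vector<int> order;        // point indices sorted by cell

  Grid(const NumericMatrix &P, double h, const Metric &m, double gx0,
       double gy0, double gLx, double gLy) {
    toroidal = m.toroidal;
    x0 = gx0;
    y0 = gy0;
    if (toroidal) {
      // cells must tile the torus exactly
      ncx = std::max(1, (int)std::floor(gLx / h));
      ncy = std::max(1, (int)std::floor(gLy / h));
      hx = gLx / ncx;
      hy = gLy / ncy;
    } else {
      ncx = std::max(1, (int)std::ceil(gLx / h));
      ncy = std::max(1, (int)std::ceil(gLy / h));
      hx = hy = h;
    }
    int n = P.nrow();
    std::vector<int> cell(n);
    std::vector<int> count(ncx * ncy + 1, 0);
    for (int i = 0; i < n; ++i) {
      cell[i] = cell_of(P(i, 0), P(i, 1));
      count[cell[i] + 1]++;
    }
    cell_start.assign(ncx * ncy + 1, 0);
    for (int c = 1; c <= ncx * ncy; ++c)
      cell_start[c] = cell_start[c - 1] + count[c];
    std::vector<int> fill(cell_start.begin(), cell_start.end() - 1);
    order.assign(n, 0);
    for (int i = 0; i < n; ++i) order[fill[cell[i]]++] = i;
  }

  int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  int cell_of(double x, double y) const {
    int cx = (int)std::floor((x - x0) / hx);
    int cy = (int)std::floor((y - y0) / hy);
    if (toroidal) {
      cx = ((cx % ncx) + ncx) % ncx;
      cy = ((cy % ncy) + ncy) % ncy;
    } else {
      cx = clampi(cx, 0, ncx - 1);
      cy = clampi(cy, 0, ncy - 1);
    }
    return cy * ncx + cx;
  }

  // visit point indices in cells within Chebyshev cell-range m of (cx, cy)
  template <class F>
  void visit_ring_box(int cx, int cy, int m, F f) const {
    for (int dy = -m; dy <= m; ++dy) {
      for (int dx = -m; dx <= m; ++dx) {
        int gx = cx + dx, gy = cy + dy;
        if (toroidal) {
          gx = ((gx % ncx) + ncx) % ncx;
          gy = ((gy % ncy) + ncy) % ncy;
        } else if (gx < 0 || gx >= ncx || gy < 0 || gy >= ncy) {
          continue;
        }
        int c = gy * ncx + gx;
        for (int k = cell_start[c]; k < cell_start[c + 1]; ++k) f(order[k]);
      }
    }
  }

  // visit only the ring at Chebyshev distance exactly m
  template <class F>
  void visit_ring(int cx, int cy, int m, F f) const {
    if (m == 0) {
      visit_ring_box(cx, cy, 0, f);
      return;
    }
    for (int dy = -m; dy <= m; ++dy) {
      for (int dx = -m; dx <= m; ++dx) {
        if (std::abs(dx) != m && std::abs(dy) != m) continue;
        int gx = cx + dx, gy = cy + dy;
        if (toroidal) {
          if (2 * m + 1 > ncx || 2 * m + 1 > ncy) {
            // ring wraps onto itself; fall back handled by caller bounds
          }
          gx = ((gx % ncx) + ncx) % ncx;
          gy = ((gy % ncy) + ncy) % ncy;
        } else if (gx < 0 || gx >= ncx || gy < 0 || gy >= ncy) {
          continue;
        }
        int c = gy * ncx + gx;
        for (int k = cell_start[c]; k < cell_start[c + 1]; ++k) f(order[k]);
      }
    }
  }
};

inline double col3(const NumericMatrix &P, int i, int j) {
  return j < P.ncol() ? P(i, j) : 0.0;
}

void extent_of(const NumericMatrix &A, const NumericMatrix &B, double &x0,
               double &y0, double &Lx, double &Ly) {
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < A.nrow(); ++i) {
    xmin = std::min(xmin, A(i, 0)); xmax = std::max(xmax, A(i, 0));
    ymin = std::min(ymin, A(i, 1)); ymax = std::max(ymax, A(i, 1));
  }
  for (int i = 0; i < B.nrow(); ++i) {
    xmin = std::min(xmin, B(i, 0)); xmax = std::max(xmax, B(i, 0));
    ymin = std::min(ymin, B(i, 1)); ymax = std::max(ymax, B(i, 1));
  }
  x0 = xmin; y0 = ymin;
  Lx = std::max(xmax - xmin, 1e-9);
  Ly = std::max(ymax - ymin, 1e-9);
}

// grids never get finer than Lmax/2048: degenerate or near-collinear point
// sets would otherwise explode the cell count
double grid_cell(double h, double Lx, double Ly) {
  return std::max(h, std::max(std::max(Lx, Ly) / 2048.0, 1e-9));
}

Metric make_metric(bool toroidal, NumericVector region) {
  Metric m;
  m.toroidal = toroidal;
  if (toroidal) {
    m.Lx = region[2] - region[0];
    m.Ly = region[3] - region[1];
  } else {
    m.Lx = m.Ly = 0.0;
  }
  return m;
}

}  // namespace

// Nearest-neighbour distance from each row of S to the point set T.
// region = c(x0, y0, x1, y1) is used only when toroidal.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix S, NumericMatrix T, bool toroidal,
                          NumericVector region) {
  int ns = S.nrow(), nt = T.nrow();
  NumericVector out(ns);
  if (nt == 0) stop("empty target point set");
  Metric met = make_metric(toroidal, region);
  double x0, y0, Lx, Ly;
  if (toroidal) {
    x0 = region[0]; y0 = region[1]; Lx = met.Lx; Ly = met.Ly;
  } else {
    extent_of(S, T, x0, y0, Lx, Ly);
    met.Lx = Lx; met.Ly = Ly;
  }
  if (nt < 64) {  // tiny targets: brute force beats any grid
    for (int i = 0; i < ns; ++i) {
      double best = R_PosInf;
      for (int j = 0; j < nt; ++j) {
        double d2 = met.dist2(S(i, 0), S(i, 1), col3(S, i, 2), T(j, 0),
                              T(j, 1), col3(T, j, 2));
        if (d2 < best) best = d2;
      }
      out[i] = std::sqrt(best);
    }
    return out;
  }
  double h = grid_cell(std::sqrt(Lx * Ly / std::max(nt, 1)), Lx, Ly);
  Grid g(T, h, met, x0, y0, Lx, Ly);
  int max_ring = std::max(g.ncx, g.ncy);
  double hmin = std::min(g.hx, g.hy);
  for (int i = 0; i < ns; ++i) {
    double sx = S(i, 0), sy = S(i, 1), sz = col3(S, i, 2);
    int c = g.cell_of(sx, sy), cx = c % g.ncx, cy = c / g.ncx;
    double best = R_PosInf;
    for (int m = 0; m <= max_ring; ++m) {
      g.visit_ring(cx, cy, m, [&](int j) {
        double d2 =
            met.dist2(sx, sy, sz, T(j, 0), T(j, 1), col3(T, j, 2));
        if (d2 < best) best = d2;
      });
      if (best <= (double)m * hmin * (double)m * hmin) break;
      if (toroidal && (2 * m + 1 >= g.ncx || 2 * m + 1 >= g.ncy) &&
          best < R_PosInf)
        break;  // whole torus visited
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Distance from each point of P to its k-th nearest other point in P.
// [[Rcpp::export]]
NumericVector cpp_kth_nn_dist(NumericMatrix P, int k) {
  int n = P.nrow();
  if (k < 1) stop("k must be >= 1");
  if (k >= n) stop("k must be smaller than the number of points");
  NumericVector out(n);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = P(i, 0) - P(j, 0), dy = P(i, 1) - P(j, 1),
             dz = col3(P, i, 2) - col3(P, j, 2);
      d2[m++] = dx * dx + dy * dy + dz * dz;
    }
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.begin() + m);
    out[i] = std::sqrt(d2[k - 1]);
  }
  return out;
}

// Weighted count of source-target pairs per distance bin
// [breaks[i], breaks[i+1]). breaks must be sorted ascending.
// exclude_self skips pairs with equal row index (same-set usage).
// [[Rcpp::export]]
NumericVector cpp_pair_hist(NumericMatrix S, NumericMatrix T,
                            NumericVector breaks, NumericVector ws,
                            NumericVector wt, bool exclude_self,
                            bool toroidal, NumericVector region) {
  int ns = S.nrow(), nt = T.nrow(), nb = breaks.size() - 1;
  if (nb < 1) stop("need at least two breaks");
  NumericVector out(nb);
  if (ns == 0 || nt == 0) return out;
  double rmax = breaks[nb], rmin = breaks[0];
  double rmax2 = rmax * rmax;
  Metric met = make_metric(toroidal, region);
  double x0, y0, Lx, Ly;
  if (toroidal) {
    x0 = region[0]; y0 = region[1]; Lx = met.Lx; Ly = met.Ly;
  } else {
    extent_of(S, T, x0, y0, Lx, Ly);
    met.Lx = Lx; met.Ly = Ly;
  }
  double h = grid_cell(rmax / 2.0, Lx, Ly);
  Grid g(T, h, met, x0, y0, Lx, Ly);
  int reach = (int)std::ceil(rmax / std::min(g.hx, g.hy)) + 1;
  if (toroidal) {
    reach = std::min(reach, std::max(g.ncx, g.ncy) / 2);
    reach = std::max(reach, 0);
  }
  bool wrap_full_x = toroidal && (2 * reach + 1 >= g.ncx);
  bool wrap_full_y = toroidal && (2 * reach + 1 >= g.ncy);
  const double *bp = breaks.begin();
  double bin_w = (breaks[nb] - breaks[0]) / nb;
  bool uniform_bins = true;
  for (int b = 0; b <= nb; ++b) {
    if (std::fabs(breaks[b] - (breaks[0] + b * bin_w)) > 1e-9 * (1 + bin_w)) {
      uniform_bins = false;
      break;
    }
  }
  for (int i = 0; i < ns; ++i) {
    double sx = S(i, 0), sy = S(i, 1), sz = col3(S, i, 2);
    double wsi = ws[i];
    int c = g.cell_of(sx, sy), cx = c % g.ncx, cy = c / g.ncx;
    int m = (wrap_full_x || wrap_full_y) ? std::max(g.ncx, g.ncy) : reach;
    // visit the full box once (rings would double-count on small tori)
    int seen_lo_x = wrap_full_x ? 0 : cx - m;
    int seen_hi_x = wrap_full_x ? g.ncx - 1 : cx + m;
    int seen_lo_y = wrap_full_y ? 0 : cy - m;
    int seen_hi_y = wrap_full_y ? g.ncy - 1 : cy + m;
    for (int gy = seen_lo_y; gy <= seen_hi_y; ++gy) {
      int wy = gy;
      if (toroidal) wy = ((gy % g.ncy) + g.ncy) % g.ncy;
      else if (gy < 0 || gy >= g.ncy) continue;
      for (int gx = seen_lo_x; gx <= seen_hi_x; ++gx) {
        int wx = gx;
        if (toroidal) wx = ((gx % g.ncx) + g.ncx) % g.ncx;
        else if (gx < 0 || gx >= g.ncx) continue;
        int cc = wy * g.ncx + wx;
        for (int kk = g.cell_start[cc]; kk < g.cell_start[cc + 1]; ++kk) {
          int j = g.order[kk];
          if (exclude_self && j == i) continue;
          double d2 =
              met.dist2(sx, sy, sz, T(j, 0), T(j, 1), col3(T, j, 2));
          if (d2 >= rmax2) continue;
          double d = std::sqrt(d2);
          if (d < rmin) continue;
          int b;
          if (uniform_bins) {
            b = (int)((d - rmin) / bin_w);
            if (b >= nb) b = nb - 1;
          } else {
            b = (int)(std::upper_bound(bp, bp + nb + 1, d) - bp) - 1;
          }
          if (b >= 0 && b < nb) out[b] += wsi * wt[j];
        }
      }
    }
  }
  return out;
}

// Per-source count of targets within radius r (self excluded on request).
// [[Rcpp::export]]
NumericVector cpp_count_within(NumericMatrix S, NumericMatrix T, double r,
                               bool exclude_self, bool toroidal,
                               NumericVector region) {
  int ns = S.nrow(), nt = T.nrow();
  NumericVector out(ns);
  if (nt == 0) return out;
  double r2 = r * r;
  Metric met = make_metric(toroidal, region);
  double x0, y0, Lx, Ly;
  if (toroidal) {
    x0 = region[0]; y0 = region[1]; Lx = met.Lx; Ly = met.Ly;
  } else {
    extent_of(S, T, x0, y0, Lx, Ly);
    met.Lx = Lx; met.Ly = Ly;
  }
  Grid g(T, grid_cell(r, Lx, Ly), met, x0, y0, Lx, Ly);
  for (int i = 0; i < ns; ++i) {
    double sx = S(i, 0), sy = S(i, 1), sz = col3(S, i, 2);
    int c = g.cell_of(sx, sy), cx = c % g.ncx, cy = c / g.ncx;
    int m = (int)std::ceil(r / std::min(g.hx, g.hy));
    if (toroidal && 2 * m + 1 >= std::min(g.ncx, g.ncy))
      m = std::max(g.ncx, g.ncy);
    double cnt = 0;
    std::vector<char> dummy;
    if (toroidal && 2 * m + 1 >= std::min(g.ncx, g.ncy)) {
      // small torus: count all points once
      for (int j = 0; j < nt; ++j) {
        if (exclude_self && j == i) continue;
        double d2 = met.dist2(sx, sy, sz, T(j, 0), T(j, 1), col3(T, j, 2));
        if (d2 <= r2) cnt += 1;
      }
    } else {
      g.visit_ring_box(cx, cy, m, [&](int j) {
        if (exclude_self && j == i) return;
        double d2 = met.dist2(sx, sy, sz, T(j, 0), T(j, 1), col3(T, j, 2));
        if (d2 <= r2) cnt += 1;
      });
    }
    out[i] = cnt;
  }
  return out;
}

// DBSCAN with self-inclusive neighbour counts (|N_eps(p)| >= k, counting p).
// Returns 0 for noise, 1..n_clusters otherwise, plus per-point roles
// (0 = noise, 1 = edge, 2 = core). Deterministic: points are expanded in
// index order and edge points join the first cluster that reaches them.
// [[Rcpp::export]]
List cpp_dbscan(NumericMatrix P, double eps, int k) {
  int n = P.nrow();
  Metric met; met.toroidal = false;
  double x0, y0, Lx, Ly;
  extent_of(P, P, x0, y0, Lx, Ly);
  met.Lx = Lx; met.Ly = Ly;
  Grid g(P, grid_cell(eps, Lx, Ly), met, x0, y0, Lx, Ly);
  double eps2 = eps * eps;
  int m = (int)std::ceil(eps / std::min(g.hx, g.hy));

  auto neighbours = [&](int i, std::vector<int> &nb) {
    nb.clear();
    double sx = P(i, 0), sy = P(i, 1), sz = col3(P, i, 2);
    int c = g.cell_of(sx, sy), cx = c % g.ncx, cy = c / g.ncx;
    g.visit_ring_box(cx, cy, m, [&](int j) {
      double d2 = met.dist2(sx, sy, sz, P(j, 0), P(j, 1), col3(P, j, 2));
      if (d2 <= eps2) nb.push_back(j);
    });
    std::sort(nb.begin(), nb.end());
  };

  std::vector<char> core(n, 0);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    neighbours(i, nb);
    if ((int)nb.size() >= k) core[i] = 1;  // neighbourhood includes i itself
  }
  IntegerVector label(n, 0);
  IntegerVector role(n, 0);
  int cl = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || label[i] != 0) continue;
    ++cl;
    stack.push_back(i);
    label[i] = cl;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      if (!core[p]) continue;
      role[p] = 2;
      neighbours(p, nb);
      for (int j : nb) {
        if (label[j] == 0) {
          label[j] = cl;
          if (core[j]) stack.push_back(j);
          else role[j] = 1;
        }
      }
    }
  }
  return List::create(_["label"] = label, _["role"] = role);
}

// Canonical OPTICS ordering with unbounded eps. core distance of p is the
// distance to its minpts-th closest *other* point; reachability of q from p is
// max(core(p), d(p, q)). Ties in the seed selection break toward the lowest
// original index. O(n^2) time, O(n) memory.
// [[Rcpp::export]]
List cpp_optics(NumericMatrix P, int minpts) {
  int n = P.nrow();
  if (minpts < 1 || minpts >= n)
    stop("minpts must be in [1, n-1]");
  NumericVector core = cpp_kth_nn_dist(P, minpts);
  std::vector<char> done(n, 0);
  NumericVector reach(n, R_PosInf);
  IntegerVector ord(n);
  NumericVector reach_out(n);
  for (int step = 0; step < n; ++step) {
    int p = -1;
    double best = R_PosInf;
    for (int i = 0; i < n; ++i) {
      if (done[i]) continue;
      if (reach[i] < best || p == -1) {
        best = reach[i];
        p = i;
      }
    }
    done[p] = 1;
    ord[step] = p + 1;
    reach_out[step] = reach[p];
    double px = P(p, 0), py = P(p, 1), pz = col3(P, p, 2);
    double cp = core[p];
    for (int q = 0; q < n; ++q) {
      if (done[q]) continue;
      double dx = px - P(q, 0), dy = py - P(q, 1), dz = pz - col3(P, q, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double r = std::max(cp, d);
      if (r < reach[q]) reach[q] = r;
    }
  }
  return List::create(_["order"] = ord, _["reachability"] = reach_out,
                      _["core_distance"] = core);
}

// Boundary-inclusive point-in-polygon (ray casting + on-segment test).
// [[Rcpp::export]]
LogicalVector cpp_in_polygon(NumericVector px, NumericVector py,
                             NumericVector vx, NumericVector vy) {
  int n = px.size(), nv = vx.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = px[i], y = py[i];
    bool inside = false, on = false;
    for (int a = 0, b = nv - 1; a < nv; b = a++) {
      double xa = vx[a], ya = vy[a], xb = vx[b], yb = vy[b];
      // on-segment check
      double cross = (xb - xa) * (y - ya) - (yb - ya) * (x - xa);
      if (std::fabs(cross) < 1e-9 * (std::fabs(xb - xa) + std::fabs(yb - ya) + 1.0)) {
        if (x >= std::min(xa, xb) - 1e-12 && x <= std::max(xa, xb) + 1e-12 &&
            y >= std::min(ya, yb) - 1e-12 && y <= std::max(ya, yb) + 1e-12) {
          on = true;
          break;
        }
      }
      if ((ya > y) != (yb > y)) {
        double xi = xa + (y - ya) / (yb - ya) * (xb - xa);
        if (x < xi) inside = !inside;
      }
    }
    out[i] = on || inside;
  }
  return out;
}

// 8-connected labeling of a logical matrix; 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix M) {
  int nr = M.nrow(), nc = M.ncol();
  IntegerMatrix lab(nr, nc);
  int cl = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!M(i, j) || lab(i, j) != 0) continue;
      ++cl;
      stack.push_back({i, j});
      lab(i, j) = cl;
      while (!stack.empty()) {
        auto pr = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ni = pr.first + di, nj = pr.second + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (M(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = cl;
              stack.push_back({ni, nj});
            }
          }
        }
      }
    }
  }
  return lab;
}
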