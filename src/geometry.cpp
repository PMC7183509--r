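#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 2-D cross product of (ax,ay) and (bx,by)
static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

struct SegCache {
  std::vector<double> x1, y1, x2, y2, sx, sy, bxmin, bxmax, bymin, bymax;
  int n;
  SegCache(const NumericMatrix& segs) {
    n = segs.nrow();
    x1.resize(n); y1.resize(n); x2.resize(n); y2.resize(n);
    sx.resize(n); sy.resize(n);
    bxmin.resize(n); bxmax.resize(n); bymin.resize(n); bymax.resize(n);
    for (int s = 0; s < n; ++s) {
      x1[s] = segs(s, 0); y1[s] = segs(s, 1);
      x2[s] = segs(s, 2); y2[s] = segs(s, 3);
      sx[s] = x2[s] - x1[s]; sy[s] = y2[s] - y1[s];
      bxmin[s] = std::min(x1[s], x2[s]); bxmax[s] = std::max(x1[s], x2[s]);
      bymin[s] = std::min(y1[s], y2[s]); bymax[s] = std::max(y1[s], y2[s]);
    }
  }
};

// True if the chord a->b, shrunk inward by eps at both ends, crosses any wall.
static bool chord_blocked(double ax, double ay, double bx, double by,
                          const SegCache& sc, double eps) {
  double dx = bx - ax, dy = by - ay;
  double len = std::sqrt(dx * dx + dy * dy);
  if (len <= 2.0 * eps) return false;  // endpoints (nearly) coincide
  double ux = dx / len, uy = dy / len;
  double p0x = ax + eps * ux, p0y = ay + eps * uy;
  double p1x = bx - eps * ux, p1y = by - eps * uy;
  double rx = p1x - p0x, ry = p1y - p0y;
  double cxmin = std::min(p0x, p1x), cxmax = std::max(p0x, p1x);
  double cymin = std::min(p0y, p1y), cymax = std::max(p0y, p1y);
  for (int s = 0; s < sc.n; ++s) {
    if (sc.bxmax[s] < cxmin || sc.bxmin[s] > cxmax ||
        sc.bymax[s] < cymin || sc.bymin[s] > cymax) continue;
    // chord endpoints strictly on one side of the wall's line: no crossing
    double o0 = sc.sx[s] * (p0y - sc.y1[s]) - sc.sy[s] * (p0x - sc.x1[s]);
    double o1 = sc.sx[s] * (p1y - sc.y1[s]) - sc.sy[s] * (p1x - sc.x1[s]);
    if (o0 * o1 > 0.0) continue;
    // wall endpoints strictly on one side of the chord's line: no crossing
    double o2 = rx * (sc.y1[s] - p0y) - ry * (sc.x1[s] - p0x);
    double o3 = rx * (sc.y2[s] - p0y) - ry * (sc.x2[s] - p0x);
    if (o2 * o3 > 0.0) continue;
    if (o0 != 0.0 || o1 != 0.0 || o2 != 0.0 || o3 != 0.0) return true;
    // collinear: overlap check via projection onto the chord
    double rr = rx * rx + ry * ry;
    double t0 = ((sc.x1[s] - p0x) * rx + (sc.y1[s] - p0y) * ry) / rr;
    double t1 = ((sc.x2[s] - p0x) * rx + (sc.y2[s] - p0y) * ry) / rr;
    if (t0 > t1) std::swap(t0, t1);
    if (t1 >= 0.0 && t0 <= 1.0) return true;
  }
  return false;
}

// [[Rcpp::export]]
LogicalVector cpp_points_allowable(NumericMatrix pts, List rings) {
  int n = pts.nrow();
  int nr = rings.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    bool inside = false, boundary = false;
    for (int r = 0; r < nr && !boundary; ++r) {
      NumericMatrix ring = rings[r];
      int m = ring.nrow();
      for (int k = 0; k < m; ++k) {
        int k2 = (k + 1) % m;
        double x1 = ring(k, 0), y1 = ring(k, 1);
        double x2 = ring(k2, 0), y2 = ring(k2, 1);
        double cr = (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1);
        if (cr == 0.0 &&
            px >= std::min(x1, x2) && px <= std::max(x1, x2) &&
            py >= std::min(y1, y2) && py <= std::max(y1, y2)) {
          boundary = true; break;
        }
        // half-open crossing rule (even-odd over all rings)
        if ((y1 > py) != (y2 > py)) {
          double xint = x1 + (py - y1) * (x2 - x1) / (y2 - y1);
          if (px < xint) inside = !inside;
        }
      }
    }
    out[i] = inside && !boundary;
  }
  return out;
}

// Pairwise visibility + distances among one point set.
// V[i,j] = 1 iff i != j, distance <= dmax (dmax <= 0 disables the cutoff),
// and the inward-nudged chord hits no wall segment.
// [[Rcpp::export]]
List cpp_pairwise_vis(NumericMatrix pts, NumericMatrix segs,
                      double eps, double dmax) {
  int n = pts.nrow();
  SegCache sc(segs);
  IntegerMatrix V(n, n);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - pts(i, 0), dy = pts(j, 1) - pts(i, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      D(i, j) = d; D(j, i) = d;
      if (dmax > 0.0 && d > dmax) continue;
      if (!chord_blocked(pts(i, 0), pts(i, 1), pts(j, 0), pts(j, 1), sc, eps)) {
        V(i, j) = 1; V(j, i) = 1;
      }
    }
  }
  return List::create(_["V"] = V, _["D"] = D);
}

// Visibility + distances from each row of A to each row of B (LOS only).
// [[Rcpp::export]]
List cpp_cross_vis(NumericMatrix A, NumericMatrix B, NumericMatrix segs,
                   double eps) {
  int n = A.nrow(), m = B.nrow();
  SegCache sc(segs);
  IntegerMatrix V(n, m);
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      double dx = B(k, 0) - A(i, 0), dy = B(k, 1) - A(i, 1);
      D(i, k) = std::sqrt(dx * dx + dy * dy);
      if (!chord_blocked(A(i, 0), A(i, 1), B(k, 0), B(k, 1), sc, eps))
        V(i, k) = 1;
    }
  }
  return List::create(_["V"] = V, _["D"] = D);
}

// Nearest-wall query: distance, unit normal (from nearest wall point toward
// the query point), and 1-based segment index.  Ties keep the lowest index.
// [[Rcpp::export]]
NumericMatrix cpp_wall_query(NumericMatrix pts, NumericMatrix segs) {
  int n = pts.nrow(), ns = segs.nrow();
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double best = R_PosInf, bnx = 0.0, bny = 0.0;
    int bidx = 0;
    for (int s = 0; s < ns; ++s) {
      double x1 = segs(s, 0), y1 = segs(s, 1), x2 = segs(s, 2), y2 = segs(s, 3);
      double ex = x2 - x1, ey = y2 - y1;
      double ee = ex * ex + ey * ey;
      double t = 0.0;
      if (ee > 0.0) {
        t = ((px - x1) * ex + (py - y1) * ey) / ee;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      double cx = x1 + t * ex, cy = y1 + t * ey;
      double dx = px - cx, dy = py - cy;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < best) {
        best = d;
        if (d > 0.0) { bnx = dx / d; bny = dy / d; } else { bnx = 0.0; bny = 0.0; }
        bidx = s + 1;
      }
    }
    out(i, 0) = best; out(i, 1) = bnx; out(i, 2) = bny; out(i, 3) = bidx;
  }
  return out;
}

// Resolve wall crossings along the step x0 -> x1.  A crossing agent stops at
// the first hit point retracted along its motion direction, and the velocity
// component normal to the hit wall is removed.
// [[Rcpp::export]]
List cpp_resolve_collisions(NumericMatrix x0, NumericMatrix x1,
                            NumericMatrix v, NumericMatrix segs,
                            double retract) {
  int n = x0.nrow();
  SegCache sc(segs);
  NumericMatrix xn = clone(x1), vn = clone(v);
  LogicalVector hit(n);
  for (int i = 0; i < n; ++i) {
    double ax = x0(i, 0), ay = x0(i, 1);
    double bx = x1(i, 0), by = x1(i, 1);
    double rx = bx - ax, ry = by - ay;
    double len = std::sqrt(rx * rx + ry * ry);
    if (len == 0.0) continue;
    double cxmin = std::min(ax, bx), cxmax = std::max(ax, bx);
    double cymin = std::min(ay, by), cymax = std::max(ay, by);
    double tbest = R_PosInf;
    int sbest = -1;
    for (int s = 0; s < sc.n; ++s) {
      if (sc.bxmax[s] < cxmin || sc.bxmin[s] > cxmax ||
          sc.bymax[s] < cymin || sc.bymin[s] > cymax) continue;
      double sx = sc.x2[s] - sc.x1[s], sy = sc.y2[s] - sc.y1[s];
      double denom = cross2(rx, ry, sx, sy);
      if (denom == 0.0) continue;  // parallel graze: ignored
      double qpx = sc.x1[s] - ax, qpy = sc.y1[s] - ay;
      double t = cross2(qpx, qpy, sx, sy) / denom;
      double u = cross2(qpx, qpy, rx, ry) / denom;
      if (t >= 0.0 && t <= 1.0 && u >= 0.0 && u <= 1.0 && t < tbest) {
        tbest = t; sbest = s;
      }
    }
    if (sbest >= 0) {
      hit[i] = true;
      double back = tbest - retract / len;
      if (back < 0.0) back = 0.0;
      xn(i, 0) = ax + back * rx;
      xn(i, 1) = ay + back * ry;
      // wall normal oriented toward the incoming side
      double sx = sc.x2[sbest] - sc.x1[sbest], sy = sc.y2[sbest] - sc.y1[sbest];
      double nx = -sy, ny = sx;
      double nl = std::sqrt(nx * nx + ny * ny);
      if (nl > 0.0) {
        nx /= nl; ny /= nl;
        if (nx * rx + ny * ry > 0.0) { nx = -nx; ny = -ny; }
        double vd = vn(i, 0) * nx + vn(i, 1) * ny;
        vn(i, 0) -= vd * nx;
        vn(i, 1) -= vd * ny;
      } else {
        vn(i, 0) = 0.0; vn(i, 1) = 0.0;
      }
    }
  }
  return List::create(_["x"] = xn, _["v"] = vn, _["hit"] = hit);
}

// Clamp weights into [lo, 1] (returns a new matrix).
// [[Rcpp::export]]
NumericMatrix cpp_clamp_unit(NumericMatrix W, double lo) {
  NumericMatrix out = clone(W);
  int n = out.size();
  for (int i = 0; i < n; ++i) {
    if (out[i] < lo) out[i] = lo;
    else if (out[i] > 1.0) out[i] = 1.0;
  }
  return out;
}

// Invert the Gaussian swarm kernel: D' = scale * sigma * sqrt(-log W').
// Validates W' in (0, 1] in the same pass.
// [[Rcpp::export]]
NumericMatrix cpp_invert_gauss(NumericMatrix W, double sigma, double scale) {
  int n = W.size();
  NumericMatrix out(W.nrow(), W.ncol());
  for (int i = 0; i < n; ++i) {
    double w = W[i];
    if (w <= 0.0 || w > 1.0)
      stop("swarm weights must lie in (0, 1] before inversion");
    out[i] = scale * sigma * std::sqrt(-std::log(w));
  }
  return out;
}

// Invert the exponential reward kernel: D' = -kappa * log W'.
// [[Rcpp::export]]
NumericMatrix cpp_invert_exp(NumericMatrix W, double kappa) {
  int n = W.size();
  NumericMatrix out(W.nrow(), W.ncol());
  for (int i = 0; i < n; ++i) {
    double w = W[i];
    if (w <= 0.0 || w > 1.0)
      stop("reward weights must lie in (0, 1] before inversion");
    out[i] = -kappa * std::log(w);
  }
  return out;
}

// Row-normalized aggregation of signed unit-vector offset demands:
// f[i,] = sum_j V[i,j] * coef[i,j] * (tgt[j,] - x[i,]) / |tgt[j,] - x[i,]|
//         / (denom_scale * sum_j V[i,j]),
// with zero contribution from coincident points and zero rows for units
// with no visible targets.
// [[Rcpp::export]]
NumericMatrix cpp_offsets(NumericMatrix coef, IntegerMatrix V,
                          NumericMatrix x, NumericMatrix tgt,
                          double denom_scale) {
  int n = x.nrow(), m = tgt.nrow();
  NumericMatrix f(n, 2);
  for (int i = 0; i < n; ++i) {
    double accx = 0.0, accy = 0.0;
    int nv = 0;
    for (int j = 0; j < m; ++j) {
      if (V(i, j) == 0) continue;
      ++nv;
      double ux = tgt(j, 0) - x(i, 0), uy = tgt(j, 1) - x(i, 1);
      double d = std::sqrt(ux * ux + uy * uy);
      if (d == 0.0) continue;
      accx += coef(i, j) * ux / d;
      accy += coef(i, j) * uy / d;
    }
    if (nv > 0) {
      f(i, 0) = accx / (denom_scale * nv);
      f(i, 1) = accy / (denom_scale * nv);
    }
  }
  return f;
}
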