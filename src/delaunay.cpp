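#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation.
// Points are inserted one by one; the cavity (all triangles whose
// circumcircle contains the new point) is retriangulated as a fan.
// Circumcenters are cached per triangle so the containment scan is cheap.
// Caller guarantees points are pairwise distinct (deduplicated in R).

struct Tri {
  int a, b, c;      // node indices, CCW
  double cx, cy, r2; // circumcircle
  bool alive;
};

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static bool circumcircle(const std::vector<double>& px,
                         const std::vector<double>& py,
                         int a, int b, int c,
                         double& cx, double& cy, double& r2) {
  double ax = px[a], ay = py[a], bx = px[b], by = py[b], qx = px[c], qy = py[c];
  double d = 2.0 * (ax * (by - qy) + bx * (qy - ay) + qx * (ay - by));
  if (std::fabs(d) < 1e-14) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = qx * qx + qy * qy;
  cx = (a2 * (by - qy) + b2 * (qy - ay) + c2 * (ay - by)) / d;
  cy = (a2 * (qx - bx) + b2 * (ax - qx) + c2 * (bx - ax)) / d;
  double dx = ax - cx, dy = ay - cy;
  r2 = dx * dx + dy * dy;
  return true;
}

// [[Rcpp::export(name = ".cpp_delaunay")]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1);
    if (px[i] < xmin) xmin = px[i];
    if (px[i] > xmax) xmax = px[i];
    if (py[i] < ymin) ymin = py[i];
    if (py[i] > ymax) ymax = py[i];
  }
  double dx = xmax - xmin, dy = ymax - ymin;
  double dmax = std::max(dx, dy) * 20.0 + 1.0;
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  // super-triangle vertices at indices n, n+1, n+2
  px[n] = midx - dmax;     py[n] = midy - dmax;
  px[n + 1] = midx + dmax; py[n + 1] = midy - dmax;
  px[n + 2] = midx;        py[n + 2] = midy + dmax;

  std::vector<Tri> tris;
  tris.reserve(4 * (size_t)n);
  {
    Tri t; t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true;
    circumcircle(px, py, t.a, t.b, t.c, t.cx, t.cy, t.r2);
    tris.push_back(t);
  }

  std::vector<int> bad;
  std::vector<std::pair<int,int> > edges;
  for (int ip = 0; ip < n; ++ip) {
    double x = px[ip], y = py[ip];
    bad.clear();
    for (size_t it = 0; it < tris.size(); ++it) {
      if (!tris[it].alive) continue;
      double ex = x - tris[it].cx, ey = y - tris[it].cy;
      if (ex * ex + ey * ey < tris[it].r2) bad.push_back((int)it);
    }
    // boundary of cavity = edges appearing exactly once among bad triangles
    edges.clear();
    for (size_t k = 0; k < bad.size(); ++k) {
      Tri& t = tris[bad[k]];
      int e[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
      for (int j = 0; j < 3; ++j) {
        bool dup = false;
        for (size_t m = 0; m < edges.size(); ++m) {
          if (edges[m].first == e[j][1] && edges[m].second == e[j][0]) {
            edges.erase(edges.begin() + m);
            dup = true; break;
          }
        }
        if (!dup) edges.push_back(std::make_pair(e[j][0], e[j][1]));
      }
      t.alive = false;
    }
    for (size_t m = 0; m < edges.size(); ++m) {
      Tri t; t.a = edges[m].first; t.b = edges[m].second; t.c = ip;
      // keep CCW
      if (orient2d(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c]) < 0)
        std::swap(t.a, t.b);
      if (!circumcircle(px, py, t.a, t.b, t.c, t.cx, t.cy, t.r2)) {
        t.cx = 0; t.cy = 0; t.r2 = -1.0; // degenerate: never captures points
      }
      t.alive = true;
      tris.push_back(t);
    }
  }

  int count = 0;
  for (size_t it = 0; it < tris.size(); ++it)
    if (tris[it].alive && tris[it].a < n && tris[it].b < n && tris[it].c < n)
      ++count;
  IntegerMatrix out(count, 3);
  int r = 0;
  for (size_t it = 0; it < tris.size(); ++it) {
    Tri& t = tris[it];
    if (t.alive && t.a < n && t.b < n && t.c < n) {
      out(r, 0) = t.a + 1; out(r, 1) = t.b + 1; out(r, 2) = t.c + 1;
      ++r;
    }
  }
  return out;
}

// Even-odd point-in-polygon for a batch of query points.
// Polygon is a closed ring given without repeated last vertex.
// [[Rcpp::export(name = ".cpp_point_in_polygon")]]
LogicalVector cpp_point_in_polygon(NumericMatrix pts, NumericMatrix poly) {
  int n = pts.nrow(), m = poly.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    bool inside = false;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      double xj = poly(j, 0), yj = poly(j, 1);
      double xk = poly(k, 0), yk = poly(k, 1);
      if (((yj > y) != (yk > y)) &&
          (x < (xk - xj) * (y - yj) / (yk - yj) + xj))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}

// Minimum distance from each query point to a set of segments.
// [[Rcpp::export(name = ".cpp_min_dist_to_segments")]]
NumericVector cpp_min_dist_to_segments(NumericMatrix pts, NumericMatrix segs) {
  // segs columns: x1 y1 x2 y2
  int n = pts.nrow(), m = segs.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double x1 = segs(j, 0), y1 = segs(j, 1), x2 = segs(j, 2), y2 = segs(j, 3);
      double ux = x2 - x1, uy = y2 - y1;
      double L2 = ux * ux + uy * uy;
      double t = L2 > 0 ? ((x - x1) * ux + (y - y1) * uy) / L2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double dx = x - (x1 + t * ux), dy = y - (y1 + t * uy);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Do any two segments from the two sets properly intersect (or touch)?
// Used for contour simplicity / containment checks.
// [[Rcpp::export(name = ".cpp_segments_intersect")]]
LogicalVector cpp_segments_intersect(NumericMatrix a, NumericMatrix b,
                                     double eps) {
  int n = a.nrow(), m = b.nrow();
  bool hit = false;
  for (int i = 0; i < n && !hit; ++i) {
    double p1x = a(i, 0), p1y = a(i, 1), p2x = a(i, 2), p2y = a(i, 3);
    for (int j = 0; j < m; ++j) {
      double q1x = b(j, 0), q1y = b(j, 1), q2x = b(j, 2), q2y = b(j, 3);
      double d1 = orient2d(q1x, q1y, q2x, q2y, p1x, p1y);
      double d2 = orient2d(q1x, q1y, q2x, q2y, p2x, p2y);
      double d3 = orient2d(p1x, p1y, p2x, p2y, q1x, q1y);
      double d4 = orient2d(p1x, p1y, p2x, p2y, q2x, q2y);
      if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
          ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) {
        hit = true; break;
      }
    }
  }
  return LogicalVector::create(hit);
}
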