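#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation with triangle-walk point
// location, used for TIN interpolation of unevenly dense point clouds.
// Coordinates are assumed pre-centred by the R wrapper (numerical headroom).

namespace {

struct Tri {
  int v[3];   // vertices, CCW
  int nb[3];  // nb[i] = triangle opposite v[i], -1 if none
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

struct Delaunay {
  std::vector<double> px, py;
  std::vector<Tri> tris;
  int last = 0;
  std::vector<int> stamp;   // visit generation per triangle (conflict BFS)
  int curStamp = 0;

  bool incircle(const Tri &t, int p) const {
    double ax = px[t.v[0]] - px[p], ay = py[t.v[0]] - py[p];
    double bx = px[t.v[1]] - px[p], by = py[t.v[1]] - py[p];
    double cx = px[t.v[2]] - px[p], cy = py[t.v[2]] - py[p];
    double det = (ax * ax + ay * ay) * (bx * cy - cx * by)
               - (bx * bx + by * by) * (ax * cy - cx * ay)
               + (cx * cx + cy * cy) * (ax * by - bx * ay);
    return det > 0.0;
  }

  bool contains(int ti, int p) const {
    const Tri &t = tris[ti];
    for (int i = 0; i < 3; ++i) {
      int a = t.v[(i + 1) % 3], b = t.v[(i + 2) % 3];
      if (orient2d(px[a], py[a], px[b], py[b], px[p], py[p]) < 0) return false;
    }
    return true;
  }

  int locate(int p) {
    int ti = last, steps = 0, limit = 4 * (int)tris.size() + 64;
    while (steps++ < limit) {
      if (!tris[ti].alive) break;
      const Tri &t = tris[ti];
      int next = -1;
      for (int i = 0; i < 3; ++i) {
        int a = t.v[(i + 1) % 3], b = t.v[(i + 2) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], px[p], py[p]) < 0) {
          next = t.nb[i];
          break;
        }
      }
      if (next == -1) return ti;
      ti = next;
      if (ti == -1) break;
    }
    // fallback: exhaustive scan
    for (int i = (int)tris.size() - 1; i >= 0; --i)
      if (tris[i].alive && contains(i, p)) return i;
    return -1;
  }

  void insert(int p) {
    int seed = locate(p);
    if (seed == -1) return; // duplicate/degenerate; skip
    // BFS over the conflict region (the located triangle always conflicts:
    // a point inside a triangle is inside its circumcircle)
    std::vector<int> bad, stack;
    if (stamp.size() < tris.size()) stamp.resize(tris.size() + 1024, 0);
    ++curStamp;
    stack.push_back(seed);
    stamp[seed] = curStamp;
    while (!stack.empty()) {
      int ti = stack.back(); stack.pop_back();
      bad.push_back(ti);
      for (int i = 0; i < 3; ++i) {
        int q = tris[ti].nb[i];
        if (q != -1 && stamp[q] != curStamp && tris[q].alive &&
            incircle(tris[q], p)) {
          stamp[q] = curStamp;
          stack.push_back(q);
        }
      }
    }
    // cavity boundary edges
    struct BEdge { int a, b, outer, outerSlot; };
    std::vector<BEdge> edges;
    for (int ti : bad) {
      const Tri &t = tris[ti];
      for (int i = 0; i < 3; ++i) {
        int q = t.nb[i];
        if (q == -1 || stamp[q] != curStamp) {
          int slot = -1;
          if (q != -1)
            for (int j = 0; j < 3; ++j) if (tris[q].nb[j] == ti) slot = j;
          edges.push_back({t.v[(i + 1) % 3], t.v[(i + 2) % 3], q, slot});
        }
      }
    }
    for (int ti : bad) tris[ti].alive = false;
    // fan of new triangles (p, a, b); link adjacency
    std::unordered_map<long long, std::pair<int,int>> open; // vertex -> (tri, slot)
    for (const BEdge &e : edges) {
      Tri nt;
      nt.v[0] = p; nt.v[1] = e.a; nt.v[2] = e.b;
      nt.nb[0] = e.outer; nt.nb[1] = -1; nt.nb[2] = -1;
      nt.alive = true;
      int ni = tris.size();
      tris.push_back(nt);
      if (e.outer != -1 && e.outerSlot != -1) tris[e.outer].nb[e.outerSlot] = ni;
      // edge (p, a) is opposite v[2]=b -> slot 2; edge (p, b) opposite slot 1
      auto link = [&](int v, int slot) {
        auto it = open.find((long long)v);
        if (it == open.end()) open[(long long)v] = {ni, slot};
        else {
          tris[ni].nb[slot] = it->second.first;
          tris[it->second.first].nb[it->second.second] = ni;
          open.erase(it);
        }
      };
      link(e.a, 2);
      link(e.b, 1);
      last = ni;
    }
  }
};

Delaunay buildDelaunay(const NumericVector &x, const NumericVector &y) {
  int n = x.size();
  Delaunay d;
  d.px.assign(x.begin(), x.end());
  d.py.assign(y.begin(), y.end());
  double xmin = *std::min_element(d.px.begin(), d.px.end());
  double xmax = *std::max_element(d.px.begin(), d.px.end());
  double ymin = *std::min_element(d.py.begin(), d.py.end());
  double ymax = *std::max_element(d.py.begin(), d.py.end());
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) span = 1.0;
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  double M = 50.0 * span;
  // super-triangle vertices appended after the real points
  d.px.push_back(cx - 2 * M); d.py.push_back(cy - M);
  d.px.push_back(cx + 2 * M); d.py.push_back(cy - M);
  d.px.push_back(cx);         d.py.push_back(cy + 2 * M);
  Tri super;
  super.v[0] = n; super.v[1] = n + 1; super.v[2] = n + 2;
  super.nb[0] = super.nb[1] = super.nb[2] = -1;
  super.alive = true;
  d.tris.push_back(super);

  // spatially coherent insertion order (grid snake) for fast walks
  int g = std::max(1, (int)std::floor(std::sqrt((double)n)));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<int> gx(n), gy(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = std::min(g - 1, (int)((d.px[i] - xmin) / (span / g)));
    gy[i] = std::min(g - 1, (int)((d.py[i] - ymin) / (span / g)));
    if (gx[i] < 0) gx[i] = 0;
    if (gy[i] < 0) gy[i] = 0;
  }
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (gy[a] != gy[b]) return gy[a] < gy[b];
    bool rev = gy[a] & 1;
    if (gx[a] != gx[b]) return rev ? gx[a] > gx[b] : gx[a] < gx[b];
    return a < b;
  });
  for (int i : order) d.insert(i);
  return d;
}

} // namespace

//' Delaunay triangulation; returns a 3-column (1-based) vertex index matrix.
//' @noRd
// [[Rcpp::export(name = ".delaunay_triangles")]]
IntegerMatrix delaunay_triangles(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  Delaunay d = buildDelaunay(x, y);
  std::vector<int> keep;
  for (int i = 0; i < (int)d.tris.size(); ++i) {
    const Tri &t = d.tris[i];
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n) continue;
    keep.push_back(i);
  }
  IntegerMatrix out(keep.size(), 3);
  for (int r = 0; r < (int)keep.size(); ++r)
    for (int j = 0; j < 3; ++j) out(r, j) = d.tris[keep[r]].v[j] + 1;
  return out;
}

//' Piecewise-linear (TIN) rasterization at cell centres.
//' Raster row 0 is the top (max-y) edge; origin is the top-left corner in geo
//' coordinates. Triangles with an edge longer than max_edge are skipped
//' (set max_edge <= 0 to disable the cap). Cells not covered stay NA.
//' @noRd
// [[Rcpp::export(name = ".tin_rasterize")]]
NumericMatrix tin_rasterize(NumericVector x, NumericVector y, NumericVector z,
                            int nrow, int ncol,
                            double origin_x, double origin_y, double res,
                            double max_edge) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  Delaunay d = buildDelaunay(x, y);
  NumericMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), NA_REAL);
  double me2 = max_edge > 0 ? max_edge * max_edge : R_PosInf;
  for (const Tri &t : d.tris) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n) continue;
    double ax = x[t.v[0]], ay = y[t.v[0]], az = z[t.v[0]];
    double bx = x[t.v[1]], by = y[t.v[1]], bz = z[t.v[1]];
    double cx = x[t.v[2]], cy = y[t.v[2]], cz = z[t.v[2]];
    auto e2 = [](double ux, double uy, double vx, double vy) {
      double dx = vx - ux, dy = vy - uy;
      return dx * dx + dy * dy;
    };
    if (e2(ax, ay, bx, by) > me2 || e2(bx, by, cx, cy) > me2 ||
        e2(ax, ay, cx, cy) > me2)
      continue;
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-300) continue;
    double xmin = std::min({ax, bx, cx}), xmax = std::max({ax, bx, cx});
    double ymin = std::min({ay, by, cy}), ymax = std::max({ay, by, cy});
    int c0 = std::max(0, (int)std::floor((xmin - origin_x) / res - 0.5));
    int c1 = std::min(ncol - 1, (int)std::ceil((xmax - origin_x) / res));
    int r0 = std::max(0, (int)std::floor((origin_y - ymax) / res - 0.5));
    int r1 = std::min(nrow - 1, (int)std::ceil((origin_y - ymin) / res));
    for (int r = r0; r <= r1; ++r) {
      double py = origin_y - (r + 0.5) * res;
      for (int c = c0; c <= c1; ++c) {
        double px = origin_x + (c + 0.5) * res;
        double w0 = ((bx - px) * (cy - py) - (by - py) * (cx - px)) / det;
        double w1 = ((cx - px) * (ay - py) - (cy - py) * (ax - px)) / det;
        double w2 = 1.0 - w0 - w1;
        double eps = -1e-9;
        if (w0 >= eps && w1 >= eps && w2 >= eps)
          out(r, c) = w0 * az + w1 * bz + w2 * cz;
      }
    }
  }
  return out;
}
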