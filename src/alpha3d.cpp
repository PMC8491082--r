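#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 3D Bowyer-Watson Delaunay tetrahedralization with circumradius-alpha
// filtering; the canopy surface is the boundary of the union of kept
// tetrahedra and its area is the sum of the boundary-triangle areas.
// Input sizes are per-plot voxel representatives (a few thousand points),
// so a scan-then-BFS conflict search is sufficient.

namespace {

struct Tet {
  int v[4];
  int nb[4]; // nb[i] = tet opposite v[i]
  bool alive;
  double ccx, ccy, ccz, cr2; // circumcentre and squared circumradius
};

inline double orient3d(const double *p, const double *q, const double *r,
                       const double *s) {
  double a[3] = {q[0] - p[0], q[1] - p[1], q[2] - p[2]};
  double b[3] = {r[0] - p[0], r[1] - p[1], r[2] - p[2]};
  double c[3] = {s[0] - p[0], s[1] - p[1], s[2] - p[2]};
  return a[0] * (b[1] * c[2] - b[2] * c[1])
       - a[1] * (b[0] * c[2] - b[2] * c[0])
       + a[2] * (b[0] * c[1] - b[1] * c[0]);
}

struct Delaunay3 {
  std::vector<double> P; // 3*n coords
  std::vector<Tet> tets;

  const double *pt(int i) const { return &P[3 * i]; }

  bool circum(Tet &t) {
    // solve for circumcentre: 2 (b-a) . x = |b|^2-|a|^2 etc.
    const double *a = pt(t.v[0]), *b = pt(t.v[1]), *c = pt(t.v[2]),
                 *d = pt(t.v[3]);
    double A[9], rhs[3];
    const double *vs[3] = {b, c, d};
    for (int i = 0; i < 3; ++i) {
      for (int j = 0; j < 3; ++j) A[3 * i + j] = 2.0 * (vs[i][j] - a[j]);
      rhs[i] = (vs[i][0] * vs[i][0] + vs[i][1] * vs[i][1] + vs[i][2] * vs[i][2])
             - (a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
    }
    // Cramer
    double det = A[0] * (A[4] * A[8] - A[5] * A[7])
               - A[1] * (A[3] * A[8] - A[5] * A[6])
               + A[2] * (A[3] * A[7] - A[4] * A[6]);
    if (std::fabs(det) < 1e-30) { t.cr2 = R_PosInf; return false; }
    auto solve = [&](int col) {
      double M[9];
      std::copy(A, A + 9, M);
      M[col] = rhs[0]; M[3 + col] = rhs[1]; M[6 + col] = rhs[2];
      return (M[0] * (M[4] * M[8] - M[5] * M[7])
            - M[1] * (M[3] * M[8] - M[5] * M[6])
            + M[2] * (M[3] * M[7] - M[4] * M[6])) / det;
    };
    t.ccx = solve(0); t.ccy = solve(1); t.ccz = solve(2);
    double dx = a[0] - t.ccx, dy = a[1] - t.ccy, dz = a[2] - t.ccz;
    t.cr2 = dx * dx + dy * dy + dz * dz;
    return true;
  }

  bool inSphere(const Tet &t, int p) const {
    const double *q = pt(p);
    double dx = q[0] - t.ccx, dy = q[1] - t.ccy, dz = q[2] - t.ccz;
    return dx * dx + dy * dy + dz * dz < t.cr2;
  }

  void insert(int p) {
    int seed = -1;
    for (int i = (int)tets.size() - 1; i >= 0; --i)
      if (tets[i].alive && inSphere(tets[i], p)) { seed = i; break; }
    if (seed == -1) return; // outside all circumspheres (shouldn't happen in super-tet)
    std::vector<int> bad, stack;
    std::vector<char> mark(tets.size(), 0);
    stack.push_back(seed); mark[seed] = 1;
    while (!stack.empty()) {
      int ti = stack.back(); stack.pop_back();
      bad.push_back(ti);
      for (int i = 0; i < 4; ++i) {
        int q = tets[ti].nb[i];
        if (q != -1 && !mark[q] && tets[q].alive && inSphere(tets[q], p)) {
          mark[q] = 1; stack.push_back(q);
        }
      }
    }
    struct BFace { int a, b, c, outer, outerSlot; };
    std::vector<BFace> faces;
    for (int ti : bad) {
      const Tet &t = tets[ti];
      static const int F[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
      for (int i = 0; i < 4; ++i) {
        int q = t.nb[i];
        if (q == -1 || !mark[q]) {
          int slot = -1;
          if (q != -1)
            for (int j = 0; j < 4; ++j) if (tets[q].nb[j] == ti) slot = j;
          faces.push_back({t.v[F[i][0]], t.v[F[i][1]], t.v[F[i][2]], q, slot});
        }
      }
    }
    for (int ti : bad) tets[ti].alive = false;
    // new tets (p, face); adjacency among them via shared (edge) hash
    std::unordered_map<long long, std::pair<int, int>> open;
    auto ekey = [](int u, int v) {
      if (u > v) std::swap(u, v);
      return (long long)u * 2000003LL + v;
    };
    for (const BFace &f : faces) {
      Tet nt;
      nt.v[0] = p; nt.v[1] = f.a; nt.v[2] = f.b; nt.v[3] = f.c;
      if (orient3d(pt(nt.v[0]), pt(nt.v[1]), pt(nt.v[2]), pt(nt.v[3])) < 0)
        std::swap(nt.v[2], nt.v[3]);
      nt.nb[0] = nt.nb[1] = nt.nb[2] = nt.nb[3] = -1;
      nt.alive = true;
      circum(nt);
      int ni = tets.size();
      // locate which slot of nt faces outward (the face not containing p is
      // opposite v[0]=p, i.e. slot 0)
      nt.nb[0] = f.outer;
      tets.push_back(nt);
      if (f.outer != -1 && f.outerSlot != -1) tets[f.outer].nb[f.outerSlot] = ni;
      // faces containing p: opposite v[1], v[2], v[3]; keyed by the edge of
      // the cavity boundary they share (the two vertices != p in that face)
      for (int s = 1; s < 4; ++s) {
        int u = -1, v = -1;
        for (int j = 1; j < 4; ++j) {
          if (j == s) continue;
          if (u == -1) u = tets[ni].v[j]; else v = tets[ni].v[j];
        }
        long long k = ekey(u, v);
        auto it = open.find(k);
        if (it == open.end()) open[k] = {ni, s};
        else {
          tets[ni].nb[s] = it->second.first;
          tets[it->second.first].nb[it->second.second] = ni;
          open.erase(it);
        }
      }
    }
  }
};

} // namespace

//' Alpha-shape surface area of a 3D point set.
//' Keeps Delaunay tetrahedra with circumradius <= alpha; returns the total
//' area of boundary triangles (faces shared by exactly one kept tet).
//' alpha <= 0 means keep all (convex hull).
//' @noRd
// [[Rcpp::export(name = ".alpha_shape_area")]]
double alpha_shape_area(NumericVector x, NumericVector y, NumericVector z,
                        double alpha) {
  int n = x.size();
  if (n < 4) stop("need at least 4 points");
  Delaunay3 d;
  d.P.resize(3 * (n + 4));
  double xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y),
         zmin = min(z), zmax = max(z);
  double span = std::max({xmax - xmin, ymax - ymin, zmax - zmin, 1e-9});
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax),
         cz = 0.5 * (zmin + zmax);
  for (int i = 0; i < n; ++i) {
    d.P[3 * i] = x[i]; d.P[3 * i + 1] = y[i]; d.P[3 * i + 2] = z[i];
  }
  double M = 100.0 * span;
  double sup[4][3] = {{cx - 2 * M, cy - M, cz - M},
                      {cx + 2 * M, cy - M, cz - M},
                      {cx, cy + 2 * M, cz - M},
                      {cx, cy, cz + 2 * M}};
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 3; ++j) d.P[3 * (n + i) + j] = sup[i][j];
  Tet super;
  super.v[0] = n; super.v[1] = n + 1; super.v[2] = n + 2; super.v[3] = n + 3;
  if (orient3d(d.pt(super.v[0]), d.pt(super.v[1]), d.pt(super.v[2]),
               d.pt(super.v[3])) < 0)
    std::swap(super.v[2], super.v[3]);
  super.nb[0] = super.nb[1] = super.nb[2] = super.nb[3] = -1;
  super.alive = true;
  d.circum(super);
  d.tets.push_back(super);
  for (int i = 0; i < n; ++i) d.insert(i);

  double a2 = alpha > 0 ? alpha * alpha : R_PosInf;
  std::unordered_map<long long, int> faceCount;
  std::unordered_map<long long, std::array<int, 3>> faceVerts;
  auto fkey = [n](int a, int b, int c) {
    int v[3] = {a, b, c};
    std::sort(v, v + 3);
    return ((long long)v[0] * (n + 5) + v[1]) * (n + 5) + v[2];
  };
  static const int F[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
  for (const Tet &t : d.tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    if (t.cr2 > a2) continue;
    for (int i = 0; i < 4; ++i) {
      long long k = fkey(t.v[F[i][0]], t.v[F[i][1]], t.v[F[i][2]]);
      faceCount[k]++;
      faceVerts[k] = {t.v[F[i][0]], t.v[F[i][1]], t.v[F[i][2]]};
    }
  }
  double area = 0;
  for (auto &kv : faceCount) {
    if (kv.second != 1) continue;
    auto &fv = faceVerts[kv.first];
    const double *a = d.pt(fv[0]), *b = d.pt(fv[1]), *c = d.pt(fv[2]);
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double cxv[3] = {u[1] * v[2] - u[2] * v[1],
                     u[2] * v[0] - u[0] * v[2],
                     u[0] * v[1] - u[1] * v[0]};
    area += 0.5 * std::sqrt(cxv[0] * cxv[0] + cxv[1] * cxv[1] + cxv[2] * cxv[2]);
  }
  return area;
}
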