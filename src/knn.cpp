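#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Static 3D kd-tree over the cloud; used for the statistical outlier filter
// (mean distance of each point to its k nearest neighbours, self excluded).

namespace {

struct KdTree {
  const double *x, *y, *z;
  std::vector<int> idx;
  int n;

  double coord(int i, int axis) const {
    return axis == 0 ? x[i] : (axis == 1 ? y[i] : z[i]);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int axis = depth % 3;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, axis) < coord(b, axis); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  // max-heap of squared distances of current k best
  void query(int lo, int hi, int depth, double qx, double qy, double qz,
             int self, int k, std::priority_queue<double> &heap) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int axis = depth % 3;
    int p = idx[mid];
    if (p != self) {
      double dx = x[p] - qx, dy = y[p] - qy, dz = z[p] - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if ((int)heap.size() < k) heap.push(d2);
      else if (d2 < heap.top()) { heap.pop(); heap.push(d2); }
    }
    double qc = axis == 0 ? qx : (axis == 1 ? qy : qz);
    double diff = qc - coord(p, axis);
    int nearLo = diff <= 0 ? lo : mid + 1;
    int nearHi = diff <= 0 ? mid : hi;
    int farLo  = diff <= 0 ? mid + 1 : lo;
    int farHi  = diff <= 0 ? hi : mid;
    query(nearLo, nearHi, depth + 1, qx, qy, qz, self, k, heap);
    if ((int)heap.size() < k || diff * diff < heap.top())
      query(farLo, farHi, depth + 1, qx, qy, qz, self, k, heap);
  }
};

} // namespace

//' Mean distance from each point to its k nearest neighbours.
//' @noRd
// [[Rcpp::export(name = ".knn_mean_dist")]]
NumericVector knn_mean_dist(NumericVector x, NumericVector y, NumericVector z,
                            int k) {
  int n = x.size();
  if (k < 1) stop("k must be >= 1");
  if (n <= k) stop("cloud must contain more than k points");
  KdTree tree;
  tree.x = x.begin(); tree.y = y.begin(); tree.z = z.begin();
  tree.n = n;
  tree.idx.resize(n);
  for (int i = 0; i < n; ++i) tree.idx[i] = i;
  tree.build(0, n, 0);

  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::priority_queue<double> heap;
    tree.query(0, n, 0, x[i], y[i], z[i], i, k, heap);
    double s = 0;
    int m = heap.size();
    while (!heap.empty()) { s += std::sqrt(heap.top()); heap.pop(); }
    out[i] = s / m;
  }
  return out;
}
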