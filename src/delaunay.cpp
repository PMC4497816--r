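// Bowyer-Watson Delaunay triangulation for the point sets used throughout:
// SC neighbour graphs (Gierer moves, Willshaw Laplacian) and lattice centers.
// Input points are continuous random samples, so exact-degenerate cases
// (duplicate or perfectly cocircular points) are not expected; the in-circle
// test uses a small relative epsilon to keep near-degenerate cases stable.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
using namespace Rcpp;

struct Tri {
  int a, b, c;       // vertex indices
  double cx, cy, r2; // circumcircle
  bool alive;
};

static inline void circumcircle(const std::vector<double> &px,
                                const std::vector<double> &py, Tri &t) {
  double ax = px[t.a], ay = py[t.a];
  double bx = px[t.b], by = py[t.b];
  double cx = px[t.c], cy = py[t.c];
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) { // collinear: push circle to infinity
    t.cx = t.cy = 0.0;
    t.r2 = std::numeric_limits<double>::infinity();
    return;
  }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  t.cx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
}

// [[Rcpp::export]]
List delaunay_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());

  // super-triangle enclosing all points by a wide margin
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; i++) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  px.push_back(midx - 30.0 * dmax); py.push_back(midy - 10.0 * dmax);
  px.push_back(midx + 30.0 * dmax); py.push_back(midy - 10.0 * dmax);
  px.push_back(midx);               py.push_back(midy + 30.0 * dmax);
  int s0 = n, s1 = n + 1, s2 = n + 2;

  std::vector<Tri> tris;
  Tri super = {s0, s1, s2, 0, 0, 0, true};
  circumcircle(px, py, super);
  tris.push_back(super);

  std::vector<int> bad;
  std::map<std::pair<int, int>, int> edgeCount;
  for (int p = 0; p < n; p++) {
    bad.clear();
    edgeCount.clear();
    double pxp = px[p], pyp = py[p];
    for (size_t t = 0; t < tris.size(); t++) {
      if (!tris[t].alive) continue;
      double dx = pxp - tris[t].cx, dy = pyp - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12)) bad.push_back((int)t);
    }
    // boundary polygon = edges appearing exactly once among bad triangles
    for (int ti : bad) {
      int v[3] = {tris[ti].a, tris[ti].b, tris[ti].c};
      for (int e = 0; e < 3; e++) {
        int u = v[e], w = v[(e + 1) % 3];
        std::pair<int, int> key(std::min(u, w), std::max(u, w));
        edgeCount[key]++;
      }
      tris[ti].alive = false;
    }
    for (auto &kv : edgeCount) {
      if (kv.second != 1) continue;
      Tri nt = {kv.first.first, kv.first.second, p, 0, 0, 0, true};
      circumcircle(px, py, nt);
      tris.push_back(nt);
    }
  }

  // collect triangles not touching the super-triangle
  std::vector<int> ta, tb, tc;
  for (auto &t : tris) {
    if (!t.alive) continue;
    if (t.a >= n || t.b >= n || t.c >= n) continue;
    ta.push_back(t.a + 1); tb.push_back(t.b + 1); tc.push_back(t.c + 1);
  }
  // unique edges
  std::map<std::pair<int, int>, bool> eset;
  for (size_t i = 0; i < ta.size(); i++) {
    int v[3] = {ta[i], tb[i], tc[i]};
    for (int e = 0; e < 3; e++) {
      int u = v[e], w = v[(e + 1) % 3];
      eset[std::make_pair(std::min(u, w), std::max(u, w))] = true;
    }
  }
  IntegerVector e1(eset.size()), e2(eset.size());
  int k = 0;
  for (auto &kv : eset) { e1[k] = kv.first.first; e2[k] = kv.first.second; k++; }
  IntegerMatrix T(ta.size(), 3);
  for (size_t i = 0; i < ta.size(); i++) { T(i,0)=ta[i]; T(i,1)=tb[i]; T(i,2)=tc[i]; }
  return List::create(_["triangles"] = T, _["edges"] = cbind(e1, e2));
}
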