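// Plan-view (2.5D) Delaunay triangulation by incremental Bowyer-Watson
// insertion with walk-based point location.  Callers pre-sort points into
// a spatially coherent order so walks are short; the terrain points this
// is used on are grid-decimated (well spaced), which keeps the double
// precision in-circle predicate reliable.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
using namespace Rcpp;

struct Tri {
  int v[3];
  int adj[3];   // adj[i] is the neighbour across the edge (v[i], v[(i+1)%3])
  bool alive;
};

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static inline bool incircle(const std::vector<double>& px,
                            const std::vector<double>& py,
                            int a, int b, int c, int d) {
  // true if d strictly inside circumcircle of (a,b,c) (ccw)
  double adx = px[a] - px[d], ady = py[a] - py[d];
  double bdx = px[b] - px[d], bdy = py[b] - py[d];
  double cdx = px[c] - px[d], cdy = py[c] - py[d];
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  double det = adx * (bdy * cd - bd * cdy) -
               ady * (bdx * cd - bd * cdx) +
               ad * (bdx * cdy - bdy * cdx);
  return det > 1e-12;
}

// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double d = std::max(xmax - xmin, ymax - ymin) * 10 + 1;
  double cx = (xmin + xmax) / 2, cy = (ymin + ymax) / 2;
  px[n] = cx - 2 * d; py[n] = cy - d;
  px[n + 1] = cx + 2 * d; py[n + 1] = cy - d;
  px[n + 2] = cx; py[n + 2] = cy + 2 * d;

  std::vector<Tri> tris;
  tris.push_back({{n, n + 1, n + 2}, {-1, -1, -1}, true});
  int last = 0;

  std::vector<int> cavity, stack;
  std::vector<char> incav;

  for (int ip = 0; ip < n; ++ip) {
    // --- locate by walk ---
    int t = last;
    if (!tris[t].alive) {
      for (int k = tris.size() - 1; k >= 0; --k)
        if (tris[k].alive) { t = k; break; }
    }
    int guard = 0;
    while (true) {
      if (++guard > (int)tris.size() + 10) {
        // walk failed (numerical); linear scan
        t = -1;
        for (int k = 0; k < (int)tris.size(); ++k) {
          if (!tris[k].alive) continue;
          const Tri& T = tris[k];
          bool in = true;
          for (int e = 0; e < 3 && in; ++e)
            if (orient2d(px[T.v[e]], py[T.v[e]], px[T.v[(e + 1) % 3]],
                         py[T.v[(e + 1) % 3]], px[ip], py[ip]) < -1e-12)
              in = false;
          if (in) { t = k; break; }
        }
        if (t < 0) stop("point location failed");
        break;
      }
      const Tri& T = tris[t];
      int moved = -1;
      for (int e = 0; e < 3; ++e) {
        if (orient2d(px[T.v[e]], py[T.v[e]], px[T.v[(e + 1) % 3]],
                     py[T.v[(e + 1) % 3]], px[ip], py[ip]) < -1e-12) {
          moved = T.adj[e];
          break;
        }
      }
      if (moved < 0) break;
      t = moved;
    }
    // --- cavity (BFS over circumcircle violations) ---
    cavity.clear(); stack.clear();
    incav.assign(tris.size(), 0);
    stack.push_back(t);
    incav[t] = 1;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      cavity.push_back(c);
      for (int e = 0; e < 3; ++e) {
        int nb = tris[c].adj[e];
        if (nb < 0 || incav[nb] || !tris[nb].alive) continue;
        if (incircle(px, py, tris[nb].v[0], tris[nb].v[1], tris[nb].v[2], ip)) {
          incav[nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    // --- boundary edges of cavity ---
    struct Edge { int a, b, outer; };
    std::vector<Edge> bound;
    for (int c : cavity) {
      for (int e = 0; e < 3; ++e) {
        int nb = tris[c].adj[e];
        if (nb < 0 || !incav[nb])
          bound.push_back({tris[c].v[e], tris[c].v[(e + 1) % 3], nb});
      }
      tris[c].alive = false;
    }
    // --- fan of new triangles; link adjacency via edge map ---
    std::map<std::pair<int, int>, std::pair<int, int>> open;  // (lo,hi)->(tri, edgeidx)
    int first_new = tris.size();
    for (const Edge& ed : bound) {
      Tri nt;
      nt.v[0] = ed.a; nt.v[1] = ed.b; nt.v[2] = ip;
      nt.adj[0] = ed.outer; nt.adj[1] = -1; nt.adj[2] = -1;
      int id = tris.size();
      // fix outer neighbour's back-pointer
      if (ed.outer >= 0) {
        Tri& O = tris[ed.outer];
        for (int e = 0; e < 3; ++e)
          if ((O.v[e] == ed.b && O.v[(e + 1) % 3] == ed.a))
            O.adj[e] = id;
      }
      nt.alive = true;
      tris.push_back(nt);
      // internal edges: (b, ip) as edge1 and (ip, a) as edge2
      for (int e = 1; e <= 2; ++e) {
        int va = tris[id].v[e], vb = tris[id].v[(e + 1) % 3];
        auto key = std::make_pair(std::min(va, vb), std::max(va, vb));
        auto it = open.find(key);
        if (it == open.end()) open[key] = {id, e};
        else {
          tris[id].adj[e] = it->second.first;
          tris[it->second.first].adj[it->second.second] = id;
          open.erase(it);
        }
      }
    }
    last = first_new;
  }
  // collect triangles not touching super vertices
  std::vector<int> keep;
  for (int k = 0; k < (int)tris.size(); ++k) {
    if (!tris[k].alive) continue;
    if (tris[k].v[0] >= n || tris[k].v[1] >= n || tris[k].v[2] >= n) continue;
    keep.push_back(k);
  }
  IntegerMatrix F(keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i) {
    // counter-clockwise order
    const Tri& T = tris[keep[i]];
    if (orient2d(px[T.v[0]], py[T.v[0]], px[T.v[1]], py[T.v[1]],
                 px[T.v[2]], py[T.v[2]]) >= 0) {
      F(i, 0) = T.v[0] + 1; F(i, 1) = T.v[1] + 1; F(i, 2) = T.v[2] + 1;
    } else {
      F(i, 0) = T.v[0] + 1; F(i, 1) = T.v[2] + 1; F(i, 2) = T.v[1] + 1;
    }
  }
  return F;
}
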