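#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Percolation test: is any fluid node of the left column connected to the
// right column through 4-neighbour (von Neumann) fluid adjacency?
// Diffusive streaming is axis-aligned, so diagonal-only contact does not
// transport mass and is not counted as connected.
// [[Rcpp::export]]
bool cpp_percolates(const LogicalMatrix& grid) {
  const int nr = grid.nrow(), nc = grid.ncol();
  if (nr == 0 || nc == 0) return false;
  std::vector<char> vis((size_t)nr * nc, 0);
  std::vector<int> stack;
  stack.reserve(nr);
  for (int r = 0; r < nr; ++r)
    if (grid(r, 0)) { vis[r] = 1; stack.push_back(r); }
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int r = idx % nr, c = idx / nr;
    if (c == nc - 1) return true;
    const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int i2 = r2 + nr * c2;
      if (!vis[i2] && grid(r2, c2)) { vis[i2] = 1; stack.push_back(i2); }
    }
  }
  return false;
}

// Label 4-connected fluid components; 0 marks solid nodes.
// [[Rcpp::export]]
IntegerMatrix cpp_components(const LogicalMatrix& grid) {
  const int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) for (int r0 = 0; r0 < nr; ++r0) {
    if (!grid(r0, c0) || lab(r0, c0) != 0) continue;
    ++next;
    lab(r0, c0) = next;
    stack.push_back(r0 + nr * c0);
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      int r = idx % nr, c = idx / nr;
      const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int r2 = r + dr[k], c2 = c + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (grid(r2, c2) && lab(r2, c2) == 0) {
          lab(r2, c2) = next;
          stack.push_back(r2 + nr * c2);
        }
      }
    }
  }
  return lab;
}

// ---- Voronoi tessellation by half-plane clipping -------------------------
//
// For each site the Voronoi cell is obtained by clipping a large bounding
// square against the bisector half-plane of every other site, nearest sites
// first, stopping once no remaining site can cut the cell (its bisector is
// farther than the farthest cell vertex).  O(n^2) overall; exact for the
// few hundred tiled sites the type-B generator uses.

struct Pt { double x, y; };

static void clip_halfplane(std::vector<Pt>& poly, double mx, double my,
                           double dx, double dy) {
  // keep points p with (p - m) . d <= 0
  const size_t n = poly.size();
  if (n == 0) return;
  std::vector<Pt> out;
  out.reserve(n + 4);
  for (size_t i = 0; i < n; ++i) {
    const Pt& a = poly[i];
    const Pt& b = poly[(i + 1) % n];
    double ga = (a.x - mx) * dx + (a.y - my) * dy;
    double gb = (b.x - mx) * dx + (b.y - my) * dy;
    bool ina = ga <= 0.0, inb = gb <= 0.0;
    if (ina) out.push_back(a);
    if (ina != inb) {
      double t = ga / (ga - gb);
      out.push_back(Pt{a.x + t * (b.x - a.x), a.y + t * (b.y - a.y)});
    }
  }
  poly.swap(out);
}

// Returns one row (x1, y1, x2, y2, site) per Voronoi-cell polygon edge.
// pts: n x 2 site coordinates; the bounding box [lo, hi]^2 must enclose all
// sites with a margin larger than any cell radius of interest.
// [[Rcpp::export]]
NumericMatrix cpp_voronoi_edges(const NumericMatrix& pts, double lo, double hi) {
  const int n = pts.nrow();
  std::vector<double> edges;
  std::vector<std::pair<double,int> > order(n > 0 ? n - 1 : 0);
  for (int i = 0; i < n; ++i) {
    const double sx = pts(i, 0), sy = pts(i, 1);
    std::vector<Pt> poly;
    poly.push_back(Pt{lo, lo}); poly.push_back(Pt{hi, lo});
    poly.push_back(Pt{hi, hi}); poly.push_back(Pt{lo, hi});
    int m = 0;
    for (int j = 0; j < n; ++j) if (j != i) {
      double dx = pts(j, 0) - sx, dy = pts(j, 1) - sy;
      order[m++] = std::make_pair(dx * dx + dy * dy, j);
    }
    std::sort(order.begin(), order.end());
    for (int k = 0; k < m && !poly.empty(); ++k) {
      double d = std::sqrt(order[k].first);
      // farthest current vertex from the site
      double rmax2 = 0.0;
      for (size_t v = 0; v < poly.size(); ++v) {
        double ax = poly[v].x - sx, ay = poly[v].y - sy;
        double r2 = ax * ax + ay * ay;
        if (r2 > rmax2) rmax2 = r2;
      }
      if (0.25 * d * d > rmax2) break;  // bisector cannot reach the cell
      int j = order[k].second;
      double mx = 0.5 * (sx + pts(j, 0)), my = 0.5 * (sy + pts(j, 1));
      clip_halfplane(poly, mx, my, pts(j, 0) - sx, pts(j, 1) - sy);
    }
    const size_t v = poly.size();
    for (size_t a = 0; a < v; ++a) {
      const Pt& p = poly[a];
      const Pt& q = poly[(a + 1) % v];
      edges.push_back(p.x); edges.push_back(p.y);
      edges.push_back(q.x); edges.push_back(q.y);
      edges.push_back((double)(i + 1));
    }
  }
  const int ne = (int)(edges.size() / 5);
  NumericMatrix out(ne, 5);
  for (int e = 0; e < ne; ++e)
    for (int k = 0; k < 5; ++k) out(e, k) = edges[5 * e + k];
  colnames(out) = CharacterVector::create("x1", "y1", "x2", "y2", "site");
  return out;
}

// Distance from every node centre (col + 0.5, row + 0.5) of an L x L grid to
// the nearest segment in `segs` (rows x1, y1, x2, y2, ...).  x runs along
// columns (the transport axis), y along rows.
// [[Rcpp::export]]
NumericMatrix cpp_segment_distance_field(const NumericMatrix& segs, int L) {
  NumericMatrix dist(L, L);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  const int ne = segs.nrow();
  const double margin = (double)L;  // segments farther away can never matter
  for (int e = 0; e < ne; ++e) {
    double x1 = segs(e, 0), y1 = segs(e, 1), x2 = segs(e, 2), y2 = segs(e, 3);
    double bx1 = std::min(x1, x2), bx2 = std::max(x1, x2);
    double by1 = std::min(y1, y2), by2 = std::max(y1, y2);
    if (bx2 < -margin || bx1 > L + margin || by2 < -margin || by1 > L + margin)
      continue;
    const double ex = x2 - x1, ey = y2 - y1;
    const double len2 = ex * ex + ey * ey;
    for (int c = 0; c < L; ++c) {
      const double px = c + 0.5;
      for (int r = 0; r < L; ++r) {
        const double py = r + 0.5;
        double t = 0.0;
        if (len2 > 0.0) {
          t = ((px - x1) * ex + (py - y1) * ey) / len2;
          if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
        }
        const double qx = x1 + t * ex - px, qy = y1 + t * ey - py;
        const double d2 = qx * qx + qy * qy;
        if (d2 < dist(r, c)) dist(r, c) = d2;
      }
    }
  }
  for (int i = 0; i < L * L; ++i) dist[i] = std::sqrt(dist[i]);
  return dist;
}
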