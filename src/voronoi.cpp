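// Clipped Dirichlet (Voronoi) tessellation for survey areas of influence.
//
// Cells are built by half-plane intersection inside a large bounding box and
// then intersected with each stratum polygon (Sutherland-Hodgman, convex clip
// region = the Voronoi cell).  A pixel-counting nearest-neighbour rasterizer
// is provided as an algorithmically independent cross-check.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Poly {
  std::vector<double> x, y;
  size_t size() const { return x.size(); }
  void clear() { x.clear(); y.clear(); }
  void push(double xx, double yy) { x.push_back(xx); y.push_back(yy); }
};

double signed_area(const Poly &p) {
  double a = 0.0;
  size_t n = p.size();
  if (n < 3) return 0.0;
  for (size_t i = 0, j = n - 1; i < n; j = i++)
    a += p.x[j] * p.y[i] - p.x[i] * p.y[j];
  return 0.5 * a;
}

// keep the side a*x + b*y <= c
void clip_halfplane(const Poly &in, Poly &out, double a, double b, double c) {
  out.clear();
  size_t n = in.size();
  if (n == 0) return;
  for (size_t i = 0, j = n - 1; i < n; j = i++) {
    double fj = a * in.x[j] + b * in.y[j] - c;
    double fi = a * in.x[i] + b * in.y[i] - c;
    bool keep_j = fj <= 0.0, keep_i = fi <= 0.0;
    if (keep_j != keep_i) {
      double t = fj / (fj - fi);
      out.push(in.x[j] + t * (in.x[i] - in.x[j]),
               in.y[j] + t * (in.y[i] - in.y[j]));
    }
    if (keep_i) out.push(in.x[i], in.y[i]);
  }
  if (out.size() < 3) out.clear();
}

Poly from_matrix(const NumericMatrix &m) {
  Poly p;
  int n = m.nrow();
  // drop an explicitly closed last vertex
  if (n > 1 && m(0, 0) == m(n - 1, 0) && m(0, 1) == m(n - 1, 1)) n--;
  for (int i = 0; i < n; i++) p.push(m(i, 0), m(i, 1));
  return p;
}

// intersection area of `subject` (any simple polygon) with convex `cell`
double clip_area_convex(const Poly &subject, Poly cell) {
  if (cell.size() < 3 || subject.size() < 3) return 0.0;
  if (signed_area(cell) < 0.0) {  // ensure CCW clip region
    std::reverse(cell.x.begin(), cell.x.end());
    std::reverse(cell.y.begin(), cell.y.end());
  }
  Poly cur = subject, nxt;
  size_t n = cell.size();
  for (size_t i = 0, j = n - 1; i < n; j = i++) {
    // edge (j -> i); inside = left of edge for CCW cell
    double a = cell.y[i] - cell.y[j];
    double b = -(cell.x[i] - cell.x[j]);
    double c = a * cell.x[j] + b * cell.y[j];
    clip_halfplane(cur, nxt, a, b, c);
    std::swap(cur, nxt);
    if (cur.size() < 3) return 0.0;
  }
  return std::fabs(signed_area(cur));
}

// Voronoi cell of site i, clipped to the bounding box (convex, CCW)
Poly voronoi_cell(int i, const NumericVector &px, const NumericVector &py,
                  double x0, double x1, double y0, double y1) {
  int n = px.size();
  Poly cell;
  cell.push(x0, y0); cell.push(x1, y0); cell.push(x1, y1); cell.push(x0, y1);

  std::vector<std::pair<double, int> > nb;
  nb.reserve(n - 1);
  for (int j = 0; j < n; j++) {
    if (j == i) continue;
    double dx = px[j] - px[i], dy = py[j] - py[i];
    nb.push_back(std::make_pair(dx * dx + dy * dy, j));
  }
  std::sort(nb.begin(), nb.end());

  Poly tmp;
  double maxr2 = 0.0;
  for (size_t v = 0; v < cell.size(); v++) {
    double dx = cell.x[v] - px[i], dy = cell.y[v] - py[i];
    maxr2 = std::max(maxr2, dx * dx + dy * dy);
  }
  for (size_t k = 0; k < nb.size(); k++) {
    if (nb[k].first > 4.0 * maxr2) break;  // bisector cannot cut the cell
    int j = nb[k].second;
    double dx = px[j] - px[i], dy = py[j] - py[i];
    double mx = 0.5 * (px[i] + px[j]), my = 0.5 * (py[i] + py[j]);
    clip_halfplane(cell, tmp, dx, dy, dx * mx + dy * my);
    std::swap(cell, tmp);
    if (cell.size() < 3) { cell.clear(); break; }
    maxr2 = 0.0;
    for (size_t v = 0; v < cell.size(); v++) {
      double ex = cell.x[v] - px[i], ey = cell.y[v] - py[i];
      maxr2 = std::max(maxr2, ex * ex + ey * ey);
    }
  }
  return cell;
}

}  // namespace

// [[Rcpp::export(name = ".voronoi_weights_cpp")]]
NumericVector voronoi_weights_cpp(NumericVector px, NumericVector py,
                                  List rings, NumericVector bbox) {
  int n = px.size();
  NumericVector w(n);
  std::vector<Poly> strata;
  std::vector<double> sx0, sx1, sy0, sy1;  // stratum bounding boxes
  for (int h = 0; h < rings.size(); h++) {
    Poly p = from_matrix(as<NumericMatrix>(rings[h]));
    double a0 = R_PosInf, a1 = R_NegInf, b0 = R_PosInf, b1 = R_NegInf;
    for (size_t v = 0; v < p.size(); v++) {
      a0 = std::min(a0, p.x[v]); a1 = std::max(a1, p.x[v]);
      b0 = std::min(b0, p.y[v]); b1 = std::max(b1, p.y[v]);
    }
    strata.push_back(p);
    sx0.push_back(a0); sx1.push_back(a1); sy0.push_back(b0); sy1.push_back(b1);
  }
  for (int i = 0; i < n; i++) {
    Poly cell = voronoi_cell(i, px, py, bbox[0], bbox[1], bbox[2], bbox[3]);
    double wi = 0.0;
    if (cell.size() >= 3) {
      double c0 = R_PosInf, c1 = R_NegInf, d0 = R_PosInf, d1 = R_NegInf;
      for (size_t v = 0; v < cell.size(); v++) {
        c0 = std::min(c0, cell.x[v]); c1 = std::max(c1, cell.x[v]);
        d0 = std::min(d0, cell.y[v]); d1 = std::max(d1, cell.y[v]);
      }
      for (size_t h = 0; h < strata.size(); h++) {
        if (sx1[h] < c0 || sx0[h] > c1 || sy1[h] < d0 || sy0[h] > d1) continue;
        wi += clip_area_convex(strata[h], cell);
      }
    }
    w[i] = wi;
  }
  return w;
}

// [[Rcpp::export(name = ".voronoi_cells_cpp")]]
List voronoi_cells_cpp(NumericVector px, NumericVector py, NumericVector bbox) {
  int n = px.size();
  List out(n);
  for (int i = 0; i < n; i++) {
    Poly cell = voronoi_cell(i, px, py, bbox[0], bbox[1], bbox[2], bbox[3]);
    NumericMatrix m(cell.size(), 2);
    for (size_t v = 0; v < cell.size(); v++) {
      m(v, 0) = cell.x[v];
      m(v, 1) = cell.y[v];
    }
    out[i] = m;
  }
  return out;
}

// [[Rcpp::export(name = ".clip_area_convex_cpp")]]
double clip_area_convex_cpp(NumericMatrix subject, NumericMatrix clip) {
  return clip_area_convex(from_matrix(subject), from_matrix(clip));
}

// [[Rcpp::export(name = ".ring_area_cpp")]]
double ring_area_cpp(NumericMatrix ring) {
  return std::fabs(signed_area(from_matrix(ring)));
}

// Independent oracle: nearest-neighbour pixel counting over the region.
// Even-odd rule over all rings decides region membership (rings must be
// non-overlapping).  Returns per-site areas (pixel count * pixel area).
// [[Rcpp::export(name = ".raster_voronoi_cpp")]]
NumericVector raster_voronoi_cpp(NumericVector px, NumericVector py,
                                 List rings, NumericVector bbox,
                                 int nx, int ny) {
  int n = px.size();
  NumericVector w(n);
  std::vector<Poly> strata;
  for (int h = 0; h < rings.size(); h++)
    strata.push_back(from_matrix(as<NumericMatrix>(rings[h])));
  double hx = (bbox[1] - bbox[0]) / nx, hy = (bbox[3] - bbox[2]) / ny;
  double cell_area = hx * hy;
  for (int iy = 0; iy < ny; iy++) {
    double yy = bbox[2] + (iy + 0.5) * hy;
    for (int ix = 0; ix < nx; ix++) {
      double xx = bbox[0] + (ix + 0.5) * hx;
      int crossings = 0;
      for (size_t h = 0; h < strata.size(); h++) {
        const Poly &p = strata[h];
        size_t m = p.size();
        for (size_t i = 0, j = m - 1; i < m; j = i++) {
          if ((p.y[i] > yy) != (p.y[j] > yy)) {
            double xint = p.x[j] + (yy - p.y[j]) / (p.y[i] - p.y[j]) *
                                       (p.x[i] - p.x[j]);
            if (xx < xint) crossings++;
          }
        }
      }
      if (crossings % 2 == 0) continue;
      int best = 0;
      double bd = R_PosInf;
      for (int s = 0; s < n; s++) {
        double dx = px[s] - xx, dy = py[s] - yy;
        double d2 = dx * dx + dy * dy;
        if (d2 < bd) { bd = d2; best = s; }
      }
      w[best] += cell_area;
    }
  }
  return w;
}
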