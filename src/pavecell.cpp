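#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Geometry kernels shared by the shape descriptors, the contour repair loop
// and the mass-spring simulator. Polygons are closed implicitly (last vertex
// connects back to the first) and oriented counter-clockwise.

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// Proper + improper segment intersection test (shared endpoints excluded by
// the callers via index bookkeeping, not here).
static bool segs_intersect(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy) {
  double d1 = cross2(dx - cx, dy - cy, ax - cx, ay - cy);
  double d2 = cross2(dx - cx, dy - cy, bx - cx, by - cy);
  double d3 = cross2(bx - ax, by - ay, cx - ax, cy - ay);
  double d4 = cross2(bx - ax, by - ay, dx - ax, dy - ay);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  // collinear overlap counts as an intersection
  auto on_seg = [](double px, double py, double qx, double qy,
                   double rx, double ry) {
    return std::min(px, qx) - 1e-14 <= rx && rx <= std::max(px, qx) + 1e-14 &&
           std::min(py, qy) - 1e-14 <= ry && ry <= std::max(py, qy) + 1e-14;
  };
  if (d1 == 0 && on_seg(cx, cy, dx, dy, ax, ay)) return true;
  if (d2 == 0 && on_seg(cx, cy, dx, dy, bx, by)) return true;
  if (d3 == 0 && on_seg(ax, ay, bx, by, cx, cy)) return true;
  if (d4 == 0 && on_seg(ax, ay, bx, by, dx, dy)) return true;
  return false;
}

// Pairs of non-adjacent polygon edges that intersect; empty matrix means the
// polygon is simple. Edge i runs v[i] -> v[i+1 mod n]. 1-based indices out.
// [[Rcpp::export]]
IntegerMatrix cpp_crossing_edge_pairs(NumericMatrix poly) {
  int n = poly.nrow();
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;  // adjacent through closure
      int j2 = (j + 1) % n;
      if (segs_intersect(poly(i, 0), poly(i, 1), poly(i2, 0), poly(i2, 1),
                         poly(j, 0), poly(j, 1), poly(j2, 0), poly(j2, 1))) {
        ei.push_back(i + 1);
        ej.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}

static bool point_in_poly(double px, double py, const NumericMatrix& poly) {
  int n = poly.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1);
    double xj = poly(j, 0), yj = poly(j, 1);
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// Signed distance to the polygon boundary: positive inside, negative outside.
// [[Rcpp::export]]
NumericVector cpp_signed_dist(NumericMatrix pts, NumericMatrix poly) {
  int m = pts.nrow(), n = poly.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    double px = pts(p, 0), py = pts(p, 1);
    double best = R_PosInf;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xj = poly(j, 0), yj = poly(j, 1);
      double xi = poly(i, 0), yi = poly(i, 1);
      double ex = xi - xj, ey = yi - yj;
      double len2 = ex * ex + ey * ey;
      double t = len2 > 0 ? ((px - xj) * ex + (py - yj) * ey) / len2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      double qx = xj + t * ex - px, qy = yj + t * ey - py;
      double d = std::sqrt(qx * qx + qy * qy);
      if (d < best) best = d;
    }
    out[p] = point_in_poly(px, py, poly) ? best : -best;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_point_in_poly(NumericMatrix pts, NumericMatrix poly) {
  int m = pts.nrow();
  LogicalVector out(m);
  for (int p = 0; p < m; ++p) out[p] = point_in_poly(pts(p, 0), pts(p, 1), poly);
  return out;
}

// Damped (fully overdamped) relaxation of a linear spring network with some
// vertices fixed. Jacobi-style update: each free vertex moves by
// dt * F_i / W_i where W_i is the summed stiffness of incident springs,
// which is unconditionally contractive for dt <= ~0.5 on a spring chain.
// Terminates when the largest per-vertex force, normalised by W_i times the
// mean rest length, drops below tol.
// [[Rcpp::export]]
List cpp_relax_springs(NumericMatrix pos0, IntegerVector sa, IntegerVector sb,
                       NumericVector rest, NumericVector stiff,
                       LogicalVector fixed, double tol, int max_iter,
                       double dt) {
  int n = pos0.nrow(), m = sa.size();
  NumericMatrix pos = clone(pos0);
  std::vector<double> W(n, 0.0);
  double mean_rest = 0.0;
  for (int s = 0; s < m; ++s) {
    W[sa[s] - 1] += stiff[s];
    W[sb[s] - 1] += stiff[s];
    mean_rest += rest[s];
  }
  mean_rest = m > 0 ? mean_rest / m : 1.0;
  if (mean_rest <= 0) mean_rest = 1.0;
  std::vector<double> Fx(n), Fy(n);
  double resid = 0.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    std::fill(Fx.begin(), Fx.end(), 0.0);
    std::fill(Fy.begin(), Fy.end(), 0.0);
    for (int s = 0; s < m; ++s) {
      int a = sa[s] - 1, b = sb[s] - 1;
      double dx = pos(b, 0) - pos(a, 0), dy = pos(b, 1) - pos(a, 1);
      double len = std::sqrt(dx * dx + dy * dy);
      if (len < 1e-300) continue;
      double f = stiff[s] * (len - rest[s]) / len;
      Fx[a] += f * dx; Fy[a] += f * dy;
      Fx[b] -= f * dx; Fy[b] -= f * dy;
    }
    resid = 0.0;
    for (int i = 0; i < n; ++i) {
      if (fixed[i] || W[i] <= 0) continue;
      double r = std::sqrt(Fx[i] * Fx[i] + Fy[i] * Fy[i]) / (W[i] * mean_rest);
      if (r > resid) resid = r;
    }
    if (resid < tol) break;
    for (int i = 0; i < n; ++i) {
      if (fixed[i] || W[i] <= 0) continue;
      pos(i, 0) += dt * Fx[i] / W[i];
      pos(i, 1) += dt * Fy[i] / W[i];
    }
  }
  return List::create(_["pos"] = pos, _["iterations"] = it,
                      _["residual"] = resid);
}

// Chord admissibility for connection placement inside one cell.
// cyc: cell outline (CCW); concave: per-vertex indentation flag.
// A chord (i, j) is admitted iff
//   * i and j are not adjacent on the cycle,
//   * |v_i - v_j| <= max_len,
//   * at least one endpoint is concave,
//   * at both endpoints the chord leaves within theta_max of the inward
//     normal (dot(chord_dir, inward_normal) >= cos_max),
//   * the open chord stays inside the cell (no crossing with non-incident
//     edges, midpoint interior).
// Returns a two-column 1-based index matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_admissible_chords(NumericMatrix cyc, LogicalVector concave,
                                    double max_len, double cos_max,
                                    bool need_concave) {
  int n = cyc.nrow();
  std::vector<int> ci, cj;
  // inward normals from central-difference tangents (CCW: interior on left)
  std::vector<double> nxs(n), nys(n);
  for (int i = 0; i < n; ++i) {
    int ip = (i + n - 1) % n, in_ = (i + 1) % n;
    double tx = cyc(in_, 0) - cyc(ip, 0), ty = cyc(in_, 1) - cyc(ip, 1);
    double tl = std::sqrt(tx * tx + ty * ty);
    if (tl < 1e-300) tl = 1.0;
    nxs[i] = -ty / tl;
    nys[i] = tx / tl;
  }
  double max_len2 = max_len * max_len;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;
      if (need_concave && !concave[i] && !concave[j]) continue;
      double dx = cyc(j, 0) - cyc(i, 0), dy = cyc(j, 1) - cyc(i, 1);
      double len2 = dx * dx + dy * dy;
      if (len2 > max_len2 || len2 < 1e-300) continue;
      double len = std::sqrt(len2);
      double ux = dx / len, uy = dy / len;
      if (ux * nxs[i] + uy * nys[i] < cos_max) continue;
      if (-ux * nxs[j] - uy * nys[j] < cos_max) continue;
      // containment: midpoint inside, no crossing of non-incident edges
      double mx = cyc(i, 0) + 0.5 * dx, my = cyc(i, 1) + 0.5 * dy;
      if (!point_in_poly(mx, my, cyc)) continue;
      bool ok = true;
      for (int e = 0; e < n && ok; ++e) {
        int e2 = (e + 1) % n;
        if (e == i || e2 == i || e == j || e2 == j) continue;
        if (segs_intersect(cyc(i, 0), cyc(i, 1), cyc(j, 0), cyc(j, 1),
                           cyc(e, 0), cyc(e, 1), cyc(e2, 0), cyc(e2, 1)))
          ok = false;
      }
      if (!ok) continue;
      ci.push_back(i + 1);
      cj.push_back(j + 1);
    }
  }
  IntegerMatrix out(ci.size(), 2);
  for (size_t k = 0; k < ci.size(); ++k) {
    out(k, 0) = ci[k];
    out(k, 1) = cj[k];
  }
  return out;
}
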