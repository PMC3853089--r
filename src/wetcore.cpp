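#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic quasi-uniform points on the unit sphere (golden-section
// spiral).  Used by the Shrake-Rupley SASA estimator; fully reproducible for
// a given point count.
// ---------------------------------------------------------------------------
static std::vector<double> sphere_points(const int n) {
  std::vector<double> p(3 * (size_t)n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double th = ga * k;
    p[3 * (size_t)k + 0] = r * std::cos(th);
    p[3 * (size_t)k + 1] = r * std::sin(th);
    p[3 * (size_t)k + 2] = z;
  }
  return p;
}

// Per-atom solvent accessible surface area by test-point sampling on the
// expanded sphere of radius r_i + probe.  `subset` holds 1-based indices of
// the atoms to evaluate; all atoms act as occluders.
// [[Rcpp::export]]
NumericVector sasa_cpp(const NumericMatrix& xyz, const NumericVector& radii,
                       const double probe, const int n_points,
                       const IntegerVector& subset) {
  const int n = xyz.nrow();
  const std::vector<double> pts = sphere_points(n_points);
  const int m = subset.size();
  NumericVector out(m);

  std::vector<double> x(n), y(n), z(n), rexp(n);
  for (int j = 0; j < n; ++j) {
    x[j] = xyz(j, 0);
    y[j] = xyz(j, 1);
    z[j] = xyz(j, 2);
    rexp[j] = radii[j] + probe;
  }

  std::vector<int> nb;
  nb.reserve(256);
  for (int si = 0; si < m; ++si) {
    const int i = subset[si] - 1;
    const double ri = rexp[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double lim = ri + rexp[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    const size_t k = nb.size();
    for (int p = 0; p < n_points; ++p) {
      const double px = x[i] + ri * pts[3 * (size_t)p + 0];
      const double py = y[i] + ri * pts[3 * (size_t)p + 1];
      const double pz = z[i] + ri * pts[3 * (size_t)p + 2];
      bool free_pt = true;
      for (size_t q = 0; q < k; ++q) {
        const int j = nb[q];
        const double dx = px - x[j], dy = py - y[j], dz = pz - z[j];
        if (dx * dx + dy * dy + dz * dz < rexp[j] * rexp[j]) {
          free_pt = false;
          // heuristic: a blocker tends to block consecutive points
          if (q > 0) std::swap(nb[0], nb[q]);
          break;
        }
      }
      if (free_pt) ++acc;
    }
    out[si] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Voronoi adjacency via 2-D linear-program feasibility.
//
// Atoms a and b are Voronoi neighbours iff some point x is at least as close
// to a (== b, x on the bisector plane) as to every other atom c.  On the
// bisector plane, each "closer to a than to c" condition is a half-plane in
// the plane coordinates (u, v); adjacency is feasibility of their
// intersection.  The search is confined to a box |u|,|v| <= box around the
// midpoint (facets of real structures live close to the atoms; the box also
// bounds the LP).  Zero-width (degenerate) facets count as adjacent via the
// eps slack.
// ---------------------------------------------------------------------------
struct HP { double a, b, c; };  // a*u + b*v <= c

// Seidel-style incremental feasibility test for half-planes plus the box.
// The eps slack for degenerate facets is folded into the constraints by the
// caller (c already relaxed); `tiny` here only absorbs floating-point noise
// and is far below the relaxation scale.
static bool lp2d_feasible(std::vector<HP>& H, const double box,
                          const double tiny) {
  const double ou = 1.0, ov = 0.6180339887498949;  // generic objective
  double u = -box, v = -box;
  const size_t m = H.size();
  // deterministic shuffle (LCG) => expected-linear behaviour, reproducible
  std::vector<size_t> ord(m);
  for (size_t i = 0; i < m; ++i) ord[i] = i;
  uint64_t st = 0x9E3779B97F4A7C15ull ^ (uint64_t)(m * 2654435761u);
  for (size_t i = m; i > 1; --i) {
    st = st * 6364136223846793005ull + 1442695040888963407ull;
    const size_t j = (size_t)(st % i);
    std::swap(ord[i - 1], ord[j]);
  }
  for (size_t t = 0; t < m; ++t) {
    const HP& h = H[ord[t]];
    if (h.a * u + h.b * v <= h.c + tiny) continue;
    // current optimum violates h: optimum of the enlarged system lies on h's
    // boundary line; solve the 1-D problem there.
    const double nn2 = h.a * h.a + h.b * h.b;
    if (nn2 < 1e-300) return false;  // 0*u+0*v <= c violated => infeasible
    const double nn = std::sqrt(nn2);
    const double pu = h.a * h.c / nn2, pv = h.b * h.c / nn2;
    const double du = -h.b / nn, dv = h.a / nn;
    double tlo = -1e300, thi = 1e300;
    bool ok = true;
    auto clip = [&](double ca, double cb, double cc) -> bool {
      const double proj = ca * du + cb * dv;
      const double rhs = cc + tiny - (ca * pu + cb * pv);
      if (std::fabs(proj) < 1e-14) return rhs >= 0;
      const double tt = rhs / proj;
      if (proj > 0) { if (tt < thi) thi = tt; }
      else          { if (tt > tlo) tlo = tt; }
      return tlo <= thi;
    };
    ok = clip(1, 0, box) && clip(-1, 0, box) &&
         clip(0, 1, box) && clip(0, -1, box);
    for (size_t s = 0; s < t && ok; ++s) {
      const HP& g = H[ord[s]];
      ok = clip(g.a, g.b, g.c);
    }
    if (!ok || tlo > thi) return false;
    const double od = ou * du + ov * dv;
    double tt;
    if (od > 1e-14)       tt = tlo;
    else if (od < -1e-14) tt = thi;
    else                  tt = (tlo > -1e299) ? tlo : ((thi < 1e299) ? thi : 0.0);
    u = pu + tt * du;
    v = pv + tt * dv;
  }
  return true;
}

// Edge list of the atomic contact graph: pairs that are Voronoi neighbours
// AND within dist <= r_a + r_b + water_diam.  Returns a 2-column 1-based
// index matrix.
// [[Rcpp::export]]
IntegerMatrix voronoi_contacts_cpp(const NumericMatrix& xyz,
                                   const NumericVector& radii,
                                   const double water_diam,
                                   const double box, const double eps) {
  const int n = xyz.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2); }

  std::vector<int> ei, ej;
  std::vector<HP> H;
  H.reserve(256);

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double lim = radii[i] + radii[j] + water_diam;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > lim * lim) continue;
      const double d = std::sqrt(d2);
      if (d < 1e-9) {  // coincident centres: degenerate, count as contact
        ei.push_back(i + 1); ej.push_back(j + 1);
        continue;
      }
      dx /= d; dy /= d; dz /= d;
      // orthonormal basis (e1, e2) of the bisector plane
      double ax = 0, ay = 0, az = 1;
      if (std::fabs(dz) > 0.9) { ax = 1; az = 0; }
      double e1x = dy * az - dz * ay, e1y = dz * ax - dx * az, e1z = dx * ay - dy * ax;
      const double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
      e1x /= n1; e1y /= n1; e1z /= n1;
      const double e2x = dy * e1z - dz * e1y;
      const double e2y = dz * e1x - dx * e1z;
      const double e2z = dx * e1y - dy * e1x;
      const double mx = 0.5 * (x[i] + x[j]);
      const double my = 0.5 * (y[i] + y[j]);
      const double mz = 0.5 * (z[i] + z[j]);

      H.clear();
      bool feasible = true;
      for (int c = 0; c < n && feasible; ++c) {
        if (c == i || c == j) continue;
        const double gx = x[c] - x[i], gy = y[c] - y[i], gz = z[c] - z[i];
        const double alpha = 2.0 * (gx * e1x + gy * e1y + gz * e1z);
        const double beta  = 2.0 * (gx * e2x + gy * e2y + gz * e2z);
        const double gamma = (x[c] * x[c] + y[c] * y[c] + z[c] * z[c])
                           - (x[i] * x[i] + y[i] * y[i] + z[i] * z[i])
                           - 2.0 * (gx * mx + gy * my + gz * mz);
        const double grel = gamma + eps;   // degenerate facets count as adjacent
        const double reach = (std::fabs(alpha) + std::fabs(beta)) * box;
        if (reach <= grel) continue;           // satisfied everywhere in box
        if (grel < -reach) { feasible = false; break; }   // violated everywhere
        H.push_back({alpha, beta, grel});
      }
      if (feasible && !H.empty()) feasible = lp2d_feasible(H, box, 1e-9);
      if (feasible) { ei.push_back(i + 1); ej.push_back(j + 1); }
    }
  }

  const int ne = (int)ei.size();
  IntegerMatrix edges(ne, 2);
  for (int k = 0; k < ne; ++k) { edges(k, 0) = ei[k]; edges(k, 1) = ej[k]; }
  return edges;
}
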