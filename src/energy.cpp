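#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete-shell elastic energy of a triangulated sheet and its analytic
// gradient. Quadratic penalties on deviations of enclosed volume, facet
// areas, edge lengths and inter-facet angles from a stress-free reference:
//   U = kv/2 (V-V0)^2/V0
//     + sum_f ka/2 (A_f-A0_f)^2/A0_f
//     + sum_e ke/2 (L_e-L0_e)^2/L0_e
//     + sum_interior kth/2 (theta_e-theta0_e)^2 L0_e
// Dihedral convention: theta = pi - phi, phi the signed angle between the
// facet normals, sign from the shared-edge orientation in the first facet
// (flat = pi, convex < pi, reflex > pi).

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// [[Rcpp::export(name = ".energy_gradient_cpp")]]
List energy_gradient_cpp(NumericMatrix V, IntegerMatrix F, IntegerMatrix E,
                         IntegerMatrix IE, double V0, NumericVector A0,
                         NumericVector L0, NumericVector L0i,
                         NumericVector Th0, double kv, double ka, double ke,
                         double kth, bool want_grad) {
  const int n = V.nrow(), m = F.nrow(), ne = E.nrow(), ni = IE.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = V(i, 0); x[3 * i + 1] = V(i, 1); x[3 * i + 2] = V(i, 2);
  }
  std::vector<double> g;
  if (want_grad) g.assign(3 * n, 0.0);

  // facet normals (non-unit) and areas
  std::vector<double> N(3 * m), A(m);
  for (int f = 0; f < m; ++f) {
    const double *p1 = &x[3 * F(f, 0)], *p2 = &x[3 * F(f, 1)],
                 *p3 = &x[3 * F(f, 2)];
    double e1[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double e2[3] = {p3[0] - p1[0], p3[1] - p1[1], p3[2] - p1[2]};
    cross3(e1, e2, &N[3 * f]);
    A[f] = 0.5 * std::sqrt(N[3 * f] * N[3 * f] + N[3 * f + 1] * N[3 * f + 1] +
                           N[3 * f + 2] * N[3 * f + 2]);
    if (A[f] <= 0.0 && (ka > 0.0 || kth > 0.0))
      stop("degenerate (zero-area) facet %d in energy evaluation", f + 1);
  }

  double U_vol = 0.0, U_area = 0.0, U_edge = 0.0, U_ang = 0.0;
  double vol = NA_REAL;

  // volume term (divergence theorem against the origin)
  if (kv > 0.0) {
    double v6 = 0.0;
    for (int f = 0; f < m; ++f) {
      const double *p1 = &x[3 * F(f, 0)], *p2 = &x[3 * F(f, 1)],
                   *p3 = &x[3 * F(f, 2)];
      double c[3];
      cross3(p2, p3, c);
      v6 += p1[0] * c[0] + p1[1] * c[1] + p1[2] * c[2];
    }
    vol = v6 / 6.0;
    const double dv = vol - V0;
    U_vol = 0.5 * kv * dv * dv / V0;
    if (want_grad) {
      const double cv = kv * dv / (V0 * 6.0);
      for (int f = 0; f < m; ++f) {
        const double *p1 = &x[3 * F(f, 0)], *p2 = &x[3 * F(f, 1)],
                     *p3 = &x[3 * F(f, 2)];
        double c[3];
        cross3(p2, p3, c);
        for (int d = 0; d < 3; ++d) g[3 * F(f, 0) + d] += cv * c[d];
        cross3(p3, p1, c);
        for (int d = 0; d < 3; ++d) g[3 * F(f, 1) + d] += cv * c[d];
        cross3(p1, p2, c);
        for (int d = 0; d < 3; ++d) g[3 * F(f, 2) + d] += cv * c[d];
      }
    }
  }

  // area term
  if (ka > 0.0) {
    for (int f = 0; f < m; ++f) {
      const double da = A[f] - A0[f];
      U_area += 0.5 * ka * da * da / A0[f];
      if (want_grad) {
        const double cf = ka * da / A0[f];
        const double *p1 = &x[3 * F(f, 0)], *p2 = &x[3 * F(f, 1)],
                     *p3 = &x[3 * F(f, 2)];
        double nh[3] = {N[3 * f] / (2.0 * A[f]), N[3 * f + 1] / (2.0 * A[f]),
                        N[3 * f + 2] / (2.0 * A[f])};
        double d23[3] = {p3[0] - p2[0], p3[1] - p2[1], p3[2] - p2[2]};
        double d31[3] = {p1[0] - p3[0], p1[1] - p3[1], p1[2] - p3[2]};
        double d12[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
        double gr[3];
        cross3(nh, d23, gr);  // grad of A wrt p1 = 0.5 n x (p3-p2)
        for (int d = 0; d < 3; ++d) g[3 * F(f, 0) + d] += cf * 0.5 * gr[d];
        cross3(nh, d31, gr);
        for (int d = 0; d < 3; ++d) g[3 * F(f, 1) + d] += cf * 0.5 * gr[d];
        cross3(nh, d12, gr);
        for (int d = 0; d < 3; ++d) g[3 * F(f, 2) + d] += cf * 0.5 * gr[d];
      }
    }
  }

  // edge-length term
  if (ke > 0.0) {
    for (int e = 0; e < ne; ++e) {
      const int a = E(e, 0), b = E(e, 1);
      double d[3] = {x[3 * a] - x[3 * b], x[3 * a + 1] - x[3 * b + 1],
                     x[3 * a + 2] - x[3 * b + 2]};
      const double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      const double dl = L - L0[e];
      U_edge += 0.5 * ke * dl * dl / L0[e];
      if (want_grad && L > 0.0) {
        const double c = ke * dl / (L0[e] * L);
        for (int dd = 0; dd < 3; ++dd) {
          g[3 * a + dd] += c * d[dd];
          g[3 * b + dd] -= c * d[dd];
        }
      }
    }
  }

  // inter-facet angle term
  if (kth > 0.0) {
    for (int e = 0; e < ni; ++e) {
      const int v1 = IE(e, 0), v2 = IE(e, 1), o1 = IE(e, 2), o2 = IE(e, 3);
      const int f1 = IE(e, 4), f2 = IE(e, 5);
      const double A1 = A[f1], A2 = A[f2];
      double n1[3] = {N[3 * f1] / (2.0 * A1), N[3 * f1 + 1] / (2.0 * A1),
                      N[3 * f1 + 2] / (2.0 * A1)};
      double n2[3] = {N[3 * f2] / (2.0 * A2), N[3 * f2 + 1] / (2.0 * A2),
                      N[3 * f2 + 2] / (2.0 * A2)};
      double ev[3] = {x[3 * v2] - x[3 * v1], x[3 * v2 + 1] - x[3 * v1 + 1],
                      x[3 * v2 + 2] - x[3 * v1 + 2]};
      const double l =
          std::sqrt(ev[0] * ev[0] + ev[1] * ev[1] + ev[2] * ev[2]);
      double eh[3] = {ev[0] / l, ev[1] / l, ev[2] / l};
      double cr[3];
      cross3(n1, n2, cr);
      const double s = cr[0] * eh[0] + cr[1] * eh[1] + cr[2] * eh[2];
      const double c = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
      const double phi = std::atan2(s, c);
      const double theta = M_PI - phi;
      const double dth = theta - Th0[e];
      U_ang += 0.5 * kth * dth * dth * L0i[e];
      if (want_grad) {
        // grad theta = -grad phi; rigid-rotation decomposition of d phi
        const double coef = -kth * dth * L0i[e];  // multiplies grad phi
        // flap vertices
        const double ck1 = -l / (2.0 * A1), ck2 = -l / (2.0 * A2);
        for (int d = 0; d < 3; ++d) {
          g[3 * o1 + d] += coef * ck1 * n1[d];
          g[3 * o2 + d] += coef * ck2 * n2[d];
        }
        // edge endpoints
        double d_o1_v2[3] = {x[3 * o1] - x[3 * v2],
                             x[3 * o1 + 1] - x[3 * v2 + 1],
                             x[3 * o1 + 2] - x[3 * v2 + 2]};
        double d_v2_o2[3] = {x[3 * v2] - x[3 * o2],
                             x[3 * v2 + 1] - x[3 * o2 + 1],
                             x[3 * v2 + 2] - x[3 * o2 + 2]};
        double d_v1_o1[3] = {x[3 * v1] - x[3 * o1],
                             x[3 * v1 + 1] - x[3 * o1 + 1],
                             x[3 * v1 + 2] - x[3 * o1 + 2]};
        double d_o2_v1[3] = {x[3 * o2] - x[3 * v1],
                             x[3 * o2 + 1] - x[3 * v1 + 1],
                             x[3 * o2 + 2] - x[3 * v1 + 2]};
        const double a1v1 =
            -(d_o1_v2[0] * eh[0] + d_o1_v2[1] * eh[1] + d_o1_v2[2] * eh[2]) /
            (2.0 * A1);
        const double a2v1 =
            (d_v2_o2[0] * eh[0] + d_v2_o2[1] * eh[1] + d_v2_o2[2] * eh[2]) /
            (2.0 * A2);
        const double a1v2 =
            -(d_v1_o1[0] * eh[0] + d_v1_o1[1] * eh[1] + d_v1_o1[2] * eh[2]) /
            (2.0 * A1);
        const double a2v2 =
            (d_o2_v1[0] * eh[0] + d_o2_v1[1] * eh[1] + d_o2_v1[2] * eh[2]) /
            (2.0 * A2);
        for (int d = 0; d < 3; ++d) {
          g[3 * v1 + d] += coef * (a1v1 * n1[d] + a2v1 * n2[d]);
          g[3 * v2 + d] += coef * (a1v2 * n1[d] + a2v2 * n2[d]);
        }
      }
    }
  }

  List out = List::create(
      Named("total") = U_vol + U_area + U_edge + U_ang,
      Named("volume") = U_vol, Named("area") = U_area,
      Named("edge") = U_edge, Named("angle") = U_ang,
      Named("enclosed_volume") = vol);
  if (want_grad) {
    NumericMatrix G(n, 3);
    for (int i = 0; i < n; ++i) {
      G(i, 0) = g[3 * i]; G(i, 1) = g[3 * i + 1]; G(i, 2) = g[3 * i + 2];
    }
    out["gradient"] = G;
  }
  return out;
}
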