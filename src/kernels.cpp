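#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Quasi-static E-field inside a homogeneous spherical conductor induced by an
// external current element.
//
// For a current element with moment v (= I * dl, A*m) at position q outside
// the conductor, the induced field at an interior point r is
//
//   E(r) = (mu0 * dI/dt / 4pi) * [ -v/a + G(r) v + (r.v) grad G(r) ],
//
// where a = |r - q| and G(r) = int_0^1 dt / |t r - q| is the line integral of
// the free-space Green function along the ray from the origin to r.  The
// gradient-G terms are the contribution of the surface charge; they cancel
// the radial component of the primary field exactly, so E.r = 0 identically
// at every interior point and the result is independent of the sphere radius
// and conductivity.  G has the closed forms (u = cos angle(r, q)):
//
//   u > 0 : G = (1/r) log( q (1 + u) / (a - r + q u) )
//   u <= 0: G = (1/r) log( (a + r - q u) / (q (1 - u)) )
//
// chosen per sign of u to avoid catastrophic cancellation near u = +-1.
// ---------------------------------------------------------------------------

static inline void efield_element(const double *r, const double *q,
                                  const double *v, double *out) {
  const double rx = r[0], ry = r[1], rz = r[2];
  const double qx = q[0], qy = q[1], qz = q[2];
  double ax = rx - qx, ay = ry - qy, az = rz - qz;
  double a = std::sqrt(ax * ax + ay * ay + az * az);
  double rn = std::sqrt(rx * rx + ry * ry + rz * rz);
  double qn = std::sqrt(qx * qx + qy * qy + qz * qz);
  double rv = rx * v[0] + ry * v[1] + rz * v[2];

  if (rn < 1e-12 * qn) { // field point at the origin: G -> 1/q, grad term -> 0
    double g0 = 1.0 / qn;
    out[0] = -v[0] / a + g0 * v[0];
    out[1] = -v[1] / a + g0 * v[1];
    out[2] = -v[2] / a + g0 * v[2];
    return;
  }

  double u = (rx * qx + ry * qy + rz * qz) / (rn * qn);
  if (u > 1.0) u = 1.0;
  if (u < -1.0) u = -1.0;

  // unit vectors and shared gradients
  double irn = 1.0 / rn;
  double rhx = rx * irn, rhy = ry * irn, rhz = rz * irn;
  double iqn = 1.0 / qn;
  double qhx = qx * iqn, qhy = qy * iqn, qhz = qz * iqn;
  // grad a = (r - q)/a
  double gax = ax / a, gay = ay / a, gaz = az / a;
  // grad u = (q_hat - u r_hat)/r
  double gux = (qhx - u * rhx) * irn;
  double guy = (qhy - u * rhy) * irn;
  double guz = (qhz - u * rhz) * irn;

  double G, ggx, ggy, ggz;
  if (u > 0.0) {
    double Dn = a - rn + qn * u; // >= qn - rn > 0 for interior points
    G = irn * std::log(qn * (1.0 + u) / Dn);
    // grad G = -(G/r) r_hat + (1/r) [ grad u/(1+u) - (grad a - r_hat + q grad u)/Dn ]
    double c1 = 1.0 / (1.0 + u), c2 = 1.0 / Dn;
    ggx = -(G * irn) * rhx + irn * (gux * c1 - (gax - rhx + qn * gux) * c2);
    ggy = -(G * irn) * rhy + irn * (guy * c1 - (gay - rhy + qn * guy) * c2);
    ggz = -(G * irn) * rhz + irn * (guz * c1 - (gaz - rhz + qn * guz) * c2);
  } else {
    double Np = a + rn - qn * u; // >= a + rn > 0
    G = irn * std::log(Np / (qn * (1.0 - u)));
    double c1 = 1.0 / (1.0 - u), c2 = 1.0 / Np;
    ggx = -(G * irn) * rhx + irn * ((gax + rhx - qn * gux) * c2 + gux * c1);
    ggy = -(G * irn) * rhy + irn * ((gay + rhy - qn * guy) * c2 + guy * c1);
    ggz = -(G * irn) * rhz + irn * ((gaz + rhz - qn * guz) * c2 + guz * c1);
  }

  double ia = 1.0 / a;
  out[0] = -v[0] * ia + G * v[0] + rv * ggx;
  out[1] = -v[1] * ia + G * v[1] + rv * ggy;
  out[2] = -v[2] * ia + G * v[2] + rv * ggz;
}

// Field (geometric part, multiply by mu0*omega*/4pi outside) of a set of
// current elements at a set of interior points. points: n x 3, epos/evec: m x 3.
// [[Rcpp::export]]
NumericMatrix efield_elements_cpp(NumericMatrix points, NumericMatrix epos,
                                  NumericMatrix evec) {
  int n = points.nrow(), m = epos.nrow();
  NumericMatrix out(n, 3);
  double r[3], q[3], v[3], e[3];
  for (int j = 0; j < m; ++j) {
    q[0] = epos(j, 0); q[1] = epos(j, 1); q[2] = epos(j, 2);
    v[0] = evec(j, 0); v[1] = evec(j, 1); v[2] = evec(j, 2);
    for (int i = 0; i < n; ++i) {
      r[0] = points(i, 0); r[1] = points(i, 1); r[2] = points(i, 2);
      efield_element(r, q, v, e);
      out(i, 0) += e[0]; out(i, 1) += e[1]; out(i, 2) += e[2];
    }
  }
  return out;
}

// Dense linear operator from basis weights to stacked E vectors.
// Each "entry" k attaches element entry_elem[k] (1-based) with coefficient
// vector entry_vec[k, ] to output column entry_col[k] (1-based).
// Output has 3*n rows (x,y,z per point, point-major) and ncol columns.
// [[Rcpp::export]]
NumericMatrix efield_operator_cpp(NumericMatrix points, NumericMatrix epos,
                                  IntegerVector entry_elem,
                                  IntegerVector entry_col,
                                  NumericMatrix entry_vec, int ncol) {
  int n = points.nrow(), K = entry_elem.size();
  NumericMatrix out(3 * n, ncol);
  double r[3], q[3], v[3], e[3];
  for (int k = 0; k < K; ++k) {
    int j = entry_elem[k] - 1, c = entry_col[k] - 1;
    q[0] = epos(j, 0); q[1] = epos(j, 1); q[2] = epos(j, 2);
    v[0] = entry_vec(k, 0); v[1] = entry_vec(k, 1); v[2] = entry_vec(k, 2);
    for (int i = 0; i < n; ++i) {
      r[0] = points(i, 0); r[1] = points(i, 1); r[2] = points(i, 2);
      efield_element(r, q, v, e);
      out(3 * i, c) += e[0];
      out(3 * i + 1, c) += e[1];
      out(3 * i + 2, c) += e[2];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Analytic single-layer potential of a flat triangle:
//   I(P) = int_T dA' / |P - r'|
// Closed form of Wilton et al. (edge-wise log and arctangent terms); finite
// for any field point including points inside the triangle or on its edges.
// ---------------------------------------------------------------------------

static inline double tri_potential(const double *P, const double *v1,
                                   const double *v2, const double *v3) {
  // normal
  double e1[3] = {v2[0] - v1[0], v2[1] - v1[1], v2[2] - v1[2]};
  double e2[3] = {v3[0] - v1[0], v3[1] - v1[1], v3[2] - v1[2]};
  double nx = e1[1] * e2[2] - e1[2] * e2[1];
  double ny = e1[2] * e2[0] - e1[0] * e2[2];
  double nz = e1[0] * e2[1] - e1[1] * e2[0];
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  nx /= nn; ny /= nn; nz /= nn;
  double h = (P[0] - v1[0]) * nx + (P[1] - v1[1]) * ny + (P[2] - v1[2]) * nz;
  double rho[3] = {P[0] - h * nx, P[1] - h * ny, P[2] - h * nz};
  double ah = std::fabs(h);
  const double *V[4] = {v1, v2, v3, v1};
  double sum_log = 0.0, sum_atan = 0.0;
  double scale = std::sqrt(nn); // ~ edge length scale
  for (int i = 0; i < 3; ++i) {
    const double *A = V[i], *B = V[i + 1];
    double sx = B[0] - A[0], sy = B[1] - A[1], sz = B[2] - A[2];
    double sl = std::sqrt(sx * sx + sy * sy + sz * sz);
    if (sl < 1e-300) continue;
    sx /= sl; sy /= sl; sz /= sl;
    // outward in-plane edge normal m = s x n
    double mx = sy * nz - sz * ny;
    double my = sz * nx - sx * nz;
    double mz = sx * ny - sy * nx;
    double t0 = (A[0] - rho[0]) * mx + (A[1] - rho[1]) * my + (A[2] - rho[2]) * mz;
    double lm = (A[0] - rho[0]) * sx + (A[1] - rho[1]) * sy + (A[2] - rho[2]) * sz;
    double lp = (B[0] - rho[0]) * sx + (B[1] - rho[1]) * sy + (B[2] - rho[2]) * sz;
    double R0sq = t0 * t0 + h * h;
    double Rm = std::sqrt(R0sq + lm * lm);
    double Rp = std::sqrt(R0sq + lp * lp);
    if (R0sq < 1e-28 * scale * scale) continue; // field point on the edge line
    // log term, rearranged when the denominator would cancel
    double num = Rp + lp, den = Rm + lm;
    double lg;
    if (den > num) lg = std::log(R0sq / ((Rp - lp) * den));
    else           lg = std::log(num * (Rm - lm) / R0sq);
    sum_log += t0 * lg;
    if (ah > 1e-14 * scale) {
      sum_atan += std::atan2(t0 * lp, R0sq + ah * Rp) -
                  std::atan2(t0 * lm, R0sq + ah * Rm);
    }
  }
  return sum_log - ah * sum_atan;
}

// [[Rcpp::export]]
NumericVector tri_potential_cpp(NumericMatrix P, NumericVector v1,
                                NumericVector v2, NumericVector v3) {
  int n = P.nrow();
  NumericVector out(n);
  double p[3], a[3] = {v1[0], v1[1], v1[2]}, b[3] = {v2[0], v2[1], v2[2]},
         c[3] = {v3[0], v3[1], v3[2]};
  for (int i = 0; i < n; ++i) {
    p[0] = P(i, 0); p[1] = P(i, 1); p[2] = P(i, 2);
    out[i] = tri_potential(p, a, b, c);
  }
  return out;
}

// Pairwise kernel matrix K[t,t'] = int_t int_t' dA dA' / |r - r'| for all
// triangle pairs. Outer integral: 3-point interior quadrature (barycentric
// (2/3,1/6,1/6) cyclic, degree 2); inner integral analytic. The result is
// symmetrized to remove the outer-quadrature asymmetry.
// verts: nt x 9 matrix (v1x v1y v1z v2x ... v3z), areas: nt.
// [[Rcpp::export]]
NumericMatrix tri_pair_kernel_cpp(NumericMatrix verts, NumericVector areas) {
  int nt = verts.nrow();
  NumericMatrix K(nt, nt);
  // precompute quadrature points: 3 per triangle
  std::vector<double> qp(nt * 9);
  const double b1 = 2.0 / 3.0, b2 = 1.0 / 6.0;
  for (int t = 0; t < nt; ++t) {
    for (int k = 0; k < 3; ++k) {
      double w[3] = {b2, b2, b2};
      w[k] = b1;
      for (int d = 0; d < 3; ++d)
        qp[t * 9 + k * 3 + d] = w[0] * verts(t, d) + w[1] * verts(t, 3 + d) +
                                w[2] * verts(t, 6 + d);
    }
  }
  double v1[3], v2[3], v3[3], p[3];
  for (int s = 0; s < nt; ++s) { // source triangle (analytic integral)
    v1[0] = verts(s, 0); v1[1] = verts(s, 1); v1[2] = verts(s, 2);
    v2[0] = verts(s, 3); v2[1] = verts(s, 4); v2[2] = verts(s, 5);
    v3[0] = verts(s, 6); v3[1] = verts(s, 7); v3[2] = verts(s, 8);
    for (int t = s; t < nt; ++t) {
      double acc = 0.0;
      for (int k = 0; k < 3; ++k) {
        p[0] = qp[t * 9 + k * 3];
        p[1] = qp[t * 9 + k * 3 + 1];
        p[2] = qp[t * 9 + k * 3 + 2];
        acc += tri_potential(p, v1, v2, v3);
      }
      K(s, t) += 0.5 * acc * areas[t] / 3.0;
      K(t, s) += 0.5 * acc * areas[t] / 3.0;
    }
    // also accumulate the transpose role: source t, observer s handled when
    // the loop reaches (t as s). Diagonal gets both halves above.
  }
  // second pass for s > t roles (observer s, source t) to complete symmetrization
  for (int s = 0; s < nt; ++s) {
    v1[0] = verts(s, 0); v1[1] = verts(s, 1); v1[2] = verts(s, 2);
    v2[0] = verts(s, 3); v2[1] = verts(s, 4); v2[2] = verts(s, 5);
    v3[0] = verts(s, 6); v3[1] = verts(s, 7); v3[2] = verts(s, 8);
    for (int t = 0; t < s; ++t) {
      double acc = 0.0;
      for (int k = 0; k < 3; ++k) {
        p[0] = qp[t * 9 + k * 3];
        p[1] = qp[t * 9 + k * 3 + 1];
        p[2] = qp[t * 9 + k * 3 + 2];
        acc += tri_potential(p, v1, v2, v3);
      }
      K(s, t) += 0.5 * acc * areas[t] / 3.0;
      K(t, s) += 0.5 * acc * areas[t] / 3.0;
    }
  }
  return K;
}

// ---------------------------------------------------------------------------
// Neumann-formula inductance of a set of straight filament segments.
// Mutual terms: adaptive subdivision of the double line integral
//   M_ij = (mu0/4pi) int int dl_i . dl_j / r.
// Self terms: external partial self-inductance of a straight round wire
//   (surface current), L_self = (mu0/2pi) l (log(2l/a) - 1).
// ---------------------------------------------------------------------------

static double seg_mutual(const double *a0, const double *a1, const double *b0,
                         const double *b1, int depth) {
  double m1[3] = {0.5 * (a0[0] + a1[0]), 0.5 * (a0[1] + a1[1]), 0.5 * (a0[2] + a1[2])};
  double m2[3] = {0.5 * (b0[0] + b1[0]), 0.5 * (b0[1] + b1[1]), 0.5 * (b0[2] + b1[2])};
  double d1[3] = {a1[0] - a0[0], a1[1] - a0[1], a1[2] - a0[2]};
  double d2[3] = {b1[0] - b0[0], b1[1] - b0[1], b1[2] - b0[2]};
  double l1 = std::sqrt(d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2]);
  double l2 = std::sqrt(d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2]);
  double dx = m1[0] - m2[0], dy = m1[1] - m2[1], dz = m1[2] - m2[2];
  double dc = std::sqrt(dx * dx + dy * dy + dz * dz);
  double lmax = (l1 > l2) ? l1 : l2;
  if (dc > 5.0 * lmax || depth >= 10) {
    if (dc < 1e-12) return 0.0; // degenerate (coincident midpoints at max depth)
    return (d1[0] * d2[0] + d1[1] * d2[1] + d1[2] * d2[2]) / dc;
  }
  // split the longer segment
  if (l1 >= l2) {
    return seg_mutual(a0, m1, b0, b1, depth + 1) +
           seg_mutual(m1, a1, b0, b1, depth + 1);
  }
  return seg_mutual(a0, a1, b0, m2, depth + 1) +
         seg_mutual(a0, a1, m2, b1, depth + 1);
}

// starts, ends: m x 3. wire_radius: a. Returns inductance in henries.
// [[Rcpp::export]]
double neumann_inductance_cpp(NumericMatrix starts, NumericMatrix ends,
                              double wire_radius) {
  const double mu0_4pi = 1e-7;
  int m = starts.nrow();
  std::vector<double> S(3 * m), E(3 * m), len(m);
  for (int i = 0; i < m; ++i) {
    for (int d = 0; d < 3; ++d) {
      S[3 * i + d] = starts(i, d);
      E[3 * i + d] = ends(i, d);
    }
    double lx = E[3 * i] - S[3 * i], ly = E[3 * i + 1] - S[3 * i + 1],
           lz = E[3 * i + 2] - S[3 * i + 2];
    len[i] = std::sqrt(lx * lx + ly * ly + lz * lz);
  }
  double L = 0.0;
  for (int i = 0; i < m; ++i) {
    if (len[i] < 1e-12) continue;
    L += 2.0 * mu0_4pi * len[i] * (std::log(2.0 * len[i] / wire_radius) - 1.0);
    for (int j = i + 1; j < m; ++j) {
      if (len[j] < 1e-12) continue;
      L += 2.0 * mu0_4pi * seg_mutual(&S[3 * i], &E[3 * i], &S[3 * j], &E[3 * j], 0);
    }
  }
  return L;
}

// Minimum distance between two 3D polylines (brute force over segment pairs).
// [[Rcpp::export]]
double polyline_min_dist_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow() - 1, nb = B.nrow() - 1;
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    double p0[3] = {A(i, 0), A(i, 1), A(i, 2)};
    double p1[3] = {A(i + 1, 0), A(i + 1, 1), A(i + 1, 2)};
    double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    for (int j = 0; j < nb; ++j) {
      double q0[3] = {B(j, 0), B(j, 1), B(j, 2)};
      double q1[3] = {B(j + 1, 0), B(j + 1, 1), B(j + 1, 2)};
      double v[3] = {q1[0] - q0[0], q1[1] - q0[1], q1[2] - q0[2]};
      double w[3] = {p0[0] - q0[0], p0[1] - q0[1], p0[2] - q0[2]};
      double aa = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
      double bb = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
      double cc = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
      double dd = u[0] * w[0] + u[1] * w[1] + u[2] * w[2];
      double ee = v[0] * w[0] + v[1] * w[1] + v[2] * w[2];
      double den = aa * cc - bb * bb;
      double s, t;
      if (den < 1e-14 * aa * cc || den <= 0.0) { s = 0.0; }
      else s = (bb * ee - cc * dd) / den;
      if (s < 0.0) s = 0.0; if (s > 1.0) s = 1.0;
      t = (cc > 0.0) ? (ee + s * bb) / cc : 0.0;
      if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
      // re-clamp s for clamped t
      if (aa > 0.0) {
        s = (s * 0.0) + ((t * bb - dd) / aa);
        if (s < 0.0) s = 0.0; if (s > 1.0) s = 1.0;
      }
      double gx = w[0] + s * u[0] - t * v[0];
      double gy = w[1] + s * u[1] - t * v[1];
      double gz = w[2] + s * u[2] - t * v[2];
      double d = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (d < best) best = d;
    }
  }
  return best;
}
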