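// Boundary-element Stokes solver: single-layer (Stokeslet) formulation with
// constant force density per triangle, collocated at triangle centroids.
// Assembles the dense influence matrix and solves for the surface densities
// that realise a set of prescribed surface velocity fields.
//
// Units are SI throughout (coordinates in metres, viscosity in Pa s).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// 16-point Gauss-Legendre nodes/weights on [0, 1]
const double GL_X[16] = {
  0.0052995325041750, 0.0277124884633837, 0.0671843988060841,
  0.1222977958224985, 0.1910618777986781, 0.2709916111713863,
  0.3591982246103705, 0.4524937450811813, 0.5475062549188187,
  0.6408017753896295, 0.7290083888286137, 0.8089381222013219,
  0.8777022041775015, 0.9328156011939159, 0.9722875115366163,
  0.9947004674958250 };
const double GL_W[16] = {
  0.0135762297058770, 0.0311267619693239, 0.0475792558412464,
  0.0623144856277669, 0.0747979944082884, 0.0845782596975013,
  0.0913017075224618, 0.0947253052275343, 0.0947253052275343,
  0.0913017075224618, 0.0845782596975013, 0.0747979944082884,
  0.0623144856277669, 0.0475792558412464, 0.0311267619693239,
  0.0135762297058770 };

inline void oseen_add(double* blk, const double* x, const double* y,
                      double w) {
  // blk (3x3, col-major) += w * (I/r + rr/r^3)
  double d0 = x[0] - y[0], d1 = x[1] - y[1], d2 = x[2] - y[2];
  double r2 = d0 * d0 + d1 * d1 + d2 * d2;
  double r = std::sqrt(r2);
  double ir = w / r, ir3 = w / (r2 * r);
  blk[0] += ir + d0 * d0 * ir3;
  blk[1] += d1 * d0 * ir3;
  blk[2] += d2 * d0 * ir3;
  blk[3] += d0 * d1 * ir3;
  blk[4] += ir + d1 * d1 * ir3;
  blk[5] += d2 * d1 * ir3;
  blk[6] += d0 * d2 * ir3;
  blk[7] += d1 * d2 * ir3;
  blk[8] += ir + d2 * d2 * ir3;
}

// Integral of the Oseen kernel over the triangle that owns the collocation
// point. Split into three sub-triangles with apex at the centroid; in polar
// coordinates about the apex the 1/r singularity cancels the area Jacobian,
// leaving a smooth 1-D integral done by Gauss-Legendre.
void self_block(double* blk, const double* p, const double* a,
                const double* b, const double* c) {
  const double* e[4] = {a, b, c, a};
  for (int s = 0; s < 3; ++s) {
    const double* A = e[s];
    const double* B = e[s + 1];
    double u1[3] = {A[0] - p[0], A[1] - p[1], A[2] - p[2]};
    double dB[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double cr[3] = {u1[1] * dB[2] - u1[2] * dB[1],
                    u1[2] * dB[0] - u1[0] * dB[2],
                    u1[0] * dB[1] - u1[1] * dB[0]};
    double jac = std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
    if (jac <= 0) continue;
    for (int q = 0; q < 16; ++q) {
      double t = GL_X[q];
      double w0 = u1[0] + t * dB[0];
      double w1 = u1[1] + t * dB[1];
      double w2 = u1[2] + t * dB[2];
      double wn = std::sqrt(w0 * w0 + w1 * w1 + w2 * w2);
      double ww = GL_W[q] * jac / wn;
      double h0 = w0 / wn, h1 = w1 / wn, h2 = w2 / wn;
      blk[0] += ww * (1.0 + h0 * h0);
      blk[1] += ww * h1 * h0;
      blk[2] += ww * h2 * h0;
      blk[3] += ww * h0 * h1;
      blk[4] += ww * (1.0 + h1 * h1);
      blk[5] += ww * h2 * h1;
      blk[6] += ww * h0 * h2;
      blk[7] += ww * h1 * h2;
      blk[8] += ww * (1.0 + h2 * h2);
    }
  }
}

// Quadrature over triangle j seen from collocation point x: 3-point edge
// midpoint rule, refined by uniform 4-way subdivision when x is close.
void tri_quad(double* blk, const double* x, const double* a,
              const double* b, const double* c, double area,
              int depth) {
  if (depth > 0) {
    double ab[3] = {0.5 * (a[0] + b[0]), 0.5 * (a[1] + b[1]), 0.5 * (a[2] + b[2])};
    double bc[3] = {0.5 * (b[0] + c[0]), 0.5 * (b[1] + c[1]), 0.5 * (b[2] + c[2])};
    double ca[3] = {0.5 * (c[0] + a[0]), 0.5 * (c[1] + a[1]), 0.5 * (c[2] + a[2])};
    double a4 = 0.25 * area;
    tri_quad(blk, x, a, ab, ca, a4, depth - 1);
    tri_quad(blk, x, ab, b, bc, a4, depth - 1);
    tri_quad(blk, x, ca, bc, c, a4, depth - 1);
    tri_quad(blk, x, ab, bc, ca, a4, depth - 1);
    return;
  }
  double w = area / 3.0;
  double m1[3] = {0.5 * (a[0] + b[0]), 0.5 * (a[1] + b[1]), 0.5 * (a[2] + b[2])};
  double m2[3] = {0.5 * (b[0] + c[0]), 0.5 * (b[1] + c[1]), 0.5 * (b[2] + c[2])};
  double m3[3] = {0.5 * (c[0] + a[0]), 0.5 * (c[1] + a[1]), 0.5 * (c[2] + a[2])};
  oseen_add(blk, x, m1, w);
  oseen_add(blk, x, m2, w);
  oseen_add(blk, x, m3, w);
}

} // namespace

// Solve the single-layer system M f = u for one or more prescribed
// collocation velocity fields.  V: n x 3 vertices (m), Fc: m x 3 1-based
// triangle indices, rhs: 3m x k velocities (SI).  Returns 3m x k densities
// (force per area, SI).  The rank completion along the surface normal
// removes the incompressibility null space of the first-kind operator
// without affecting force, torque or deviatoric stresslet moments.
// [[Rcpp::export(name = ".bem_solve_cpp")]]
Rcpp::List bem_solve_cpp(const arma::mat& V, const arma::imat& Fc,
                         double eta, const arma::mat& rhs,
                         bool return_matrix = false, double alpha_scale = 1.0) {
  const uword m = Fc.n_rows;
  if (rhs.n_rows != 3 * m) Rcpp::stop("rhs must have 3 * n_triangles rows");
  mat P1(m, 3), P2(m, 3), P3(m, 3);
  for (uword j = 0; j < m; ++j) {
    P1.row(j) = V.row(Fc(j, 0) - 1);
    P2.row(j) = V.row(Fc(j, 1) - 1);
    P3.row(j) = V.row(Fc(j, 2) - 1);
  }
  mat C = (P1 + P2 + P3) / 3.0;
  mat E1 = P2 - P1, E2 = P3 - P1;
  mat Nrm(m, 3);
  vec A(m), siz(m);
  for (uword j = 0; j < m; ++j) {
    rowvec cr = cross(E1.row(j), E2.row(j));
    double nn = norm(cr);
    A(j) = 0.5 * nn;
    Nrm.row(j) = cr / nn;
    siz(j) = std::sqrt(A(j));
  }
  const double pref = 1.0 / (8.0 * M_PI * eta);
  mat M(3 * m, 3 * m, fill::zeros);
  double blk[9];
  for (uword i = 0; i < m; ++i) {
    const double* x = C.colptr(0) + i; // column-major access handled below
    double xi[3] = {C(i, 0), C(i, 1), C(i, 2)};
    (void)x;
    for (uword j = 0; j < m; ++j) {
      std::fill(blk, blk + 9, 0.0);
      double a[3] = {P1(j, 0), P1(j, 1), P1(j, 2)};
      double b[3] = {P2(j, 0), P2(j, 1), P2(j, 2)};
      double c[3] = {P3(j, 0), P3(j, 1), P3(j, 2)};
      if (i == j) {
        self_block(blk, xi, a, b, c);
      } else {
        double dx = C(j, 0) - xi[0], dy = C(j, 1) - xi[1], dz = C(j, 2) - xi[2];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        int depth = 0;
        double s = siz(i) + siz(j);
        if (d < 2.0 * s) depth = 2;
        else if (d < 4.0 * s) depth = 1;
        tri_quad(blk, xi, a, b, c, A(j), depth);
      }
      for (int cc = 0; cc < 3; ++cc)
        for (int rr = 0; rr < 3; ++rr)
          M(3 * i + rr, 3 * j + cc) = pref * blk[rr + 3 * cc];
    }
    Rcpp::checkUserInterrupt();
  }
  // rank completion: M += alpha * n(x_i) n(x_j)^T A_j
  double alpha = 0.0;
  for (uword i = 0; i < 3 * m; ++i) alpha += M(i, i);
  alpha = alpha_scale * alpha / (3.0 * m);
  for (uword j = 0; j < m; ++j)
    for (uword i = 0; i < m; ++i)
      for (int cc = 0; cc < 3; ++cc)
        for (int rr = 0; rr < 3; ++rr)
          M(3 * i + rr, 3 * j + cc) += alpha * Nrm(i, rr) * Nrm(j, cc) * A(j);
  mat sol;
  bool ok = solve(sol, M, rhs, solve_opts::no_approx);
  if (!ok) Rcpp::stop("singular boundary-element system");
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("density") = sol,
    Rcpp::Named("centroids") = C,
    Rcpp::Named("areas") = A,
    Rcpp::Named("normals") = Nrm);
  if (return_matrix) out["matrix"] = M;
  return out;
}
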