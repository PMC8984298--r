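#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Node i (0-based) sits at coordinate -L/2 + i*h along each axis; the grid
// spans the closed cube including the boundary faces where c = 1.

static inline int idx3(int i, int j, int k, int I) {
  return i + I * (j + I * k);
}

// Nearest-node binning: each agent adds one count to the node whose h-cube
// control volume contains it. Returns a density array (counts / h^3).
// [[Rcpp::export]]
NumericVector cpp_bin_density(NumericVector x, NumericVector y, NumericVector z,
                              int I, double L) {
  double h = L / (I - 1);
  double half = L / 2.0;
  int n = x.size();
  NumericVector v(I * I * I);
  for (int a = 0; a < n; ++a) {
    int i = (int) std::floor((x[a] + half) / h + 0.5);
    int j = (int) std::floor((y[a] + half) / h + 0.5);
    int k = (int) std::floor((z[a] + half) / h + 0.5);
    if (i < 0 || j < 0 || k < 0 || i >= I || j >= I || k >= I)
      stop("agent position outside the computational domain");
    v[idx3(i, j, k, I)] += 1.0;
  }
  double invh3 = 1.0 / (h * h * h);
  for (R_xlen_t q = 0; q < v.size(); ++q) v[q] *= invh3;
  v.attr("dim") = IntegerVector::create(I, I, I);
  return v;
}

// Trilinear interpolation of the nodal field at arbitrary positions.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector x, NumericVector y, NumericVector z,
                            NumericVector c, int I, double L) {
  double h = L / (I - 1);
  double half = L / 2.0;
  int n = x.size();
  NumericVector out(n);
  for (int a = 0; a < n; ++a) {
    double u = (x[a] + half) / h;
    double v = (y[a] + half) / h;
    double w = (z[a] + half) / h;
    if (u < 0 || v < 0 || w < 0 || u > I - 1 || v > I - 1 || w > I - 1)
      stop("position outside the grid");
    int i0 = std::min((int) std::floor(u), I - 2);
    int j0 = std::min((int) std::floor(v), I - 2);
    int k0 = std::min((int) std::floor(w), I - 2);
    double fx = u - i0, fy = v - j0, fz = w - k0;
    double c000 = c[idx3(i0, j0, k0, I)],     c100 = c[idx3(i0 + 1, j0, k0, I)];
    double c010 = c[idx3(i0, j0 + 1, k0, I)], c110 = c[idx3(i0 + 1, j0 + 1, k0, I)];
    double c001 = c[idx3(i0, j0, k0 + 1, I)], c101 = c[idx3(i0 + 1, j0, k0 + 1, I)];
    double c011 = c[idx3(i0, j0 + 1, k0 + 1, I)], c111 = c[idx3(i0 + 1, j0 + 1, k0 + 1, I)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[a] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Quasi-steady nutrient solve: 0 = lap(c) - alpha * v * c on the interior,
// c = 1 on the boundary faces. Seven-point finite-volume stencil; the
// Dirichlet nodes are eliminated into the right-hand side, leaving a
// symmetric positive definite M-matrix solved by conjugate gradients with
// an incomplete-Cholesky IC(0) preconditioner, optionally warm-started
// from a previous field.
//
// Implementation note: all work vectors are full-grid arrays whose
// boundary entries are pinned at zero, so the stencil applications need no
// neighbour bounds checks and the hot loops vectorize.
// [[Rcpp::export]]
List cpp_solve_nutrient(NumericVector v, int I, double h, double alpha,
                        Nullable<NumericVector> warm, double tol, int maxit) {
  const double ih2 = 1.0 / (h * h);
  const R_xlen_t II = (R_xlen_t) I * I;
  const R_xlen_t ntot = II * I;
  std::vector<double> u(ntot, 0.0), r(ntot, 0.0), z(ntot, 0.0),
                      p(ntot, 0.0), Ap(ntot, 0.0), diag(ntot, 1.0),
                      b(ntot, 0.0), dic(ntot, 1.0);

  NumericVector w0;
  bool have_warm = warm.isNotNull();
  if (have_warm) {
    w0 = warm.get();
    if ((R_xlen_t) w0.size() != ntot) stop("warm start has the wrong size");
  }
  for (int k = 1; k < I - 1; ++k)
    for (int j = 1; j < I - 1; ++j)
      for (int i = 1; i < I - 1; ++i) {
        R_xlen_t q = idx3(i, j, k, I);
        diag[q] = 6.0 * ih2 + alpha * v[q];
        int nb = (i == 1) + (i == I - 2) + (j == 1) + (j == I - 2) +
                 (k == 1) + (k == I - 2);
        b[q] = nb * ih2;           // boundary neighbours carry c = 1
        u[q] = have_warm ? w0[q] : 1.0;
      }

  // IC(0) factorization kept on the 7-point pattern: off-diagonals of the
  // lower factor are the matrix entries (-1/h^2) scaled by the already
  // computed pivots, which for the structured stencil reduces to the
  // recursion below on the pivot array. Interior-only; boundary pivots 1.
  for (int k = 1; k < I - 1; ++k)
    for (int j = 1; j < I - 1; ++j)
      for (int i = 1; i < I - 1; ++i) {
        R_xlen_t q = idx3(i, j, k, I);
        double s = diag[q];
        if (i > 1)  s -= (ih2 * ih2) / dic[q - 1];
        if (j > 1)  s -= (ih2 * ih2) / dic[q - I];
        if (k > 1)  s -= (ih2 * ih2) / dic[q - II];
        if (s <= 0) stop("incomplete factorization broke down");
        dic[q] = s;
      }
  std::vector<double> idic(ntot, 1.0);
  for (R_xlen_t q = 0; q < ntot; ++q) idic[q] = 1.0 / dic[q];

  double bnorm = 0.0;
  for (R_xlen_t q = 0; q < ntot; ++q) bnorm += b[q] * b[q];
  bnorm = std::sqrt(bnorm);

  // z = M^-1 r with M = (D + L) D^-1 (D + L)^T restricted to the pattern:
  // forward solve, diagonal scale, backward solve. Boundary entries of r
  // are zero so neighbour reads need no bounds checks beyond the loops.
  auto apply_precond = [&](const std::vector<double>& rr,
                           std::vector<double>& zz) {
    for (int k = 1; k < I - 1; ++k)
      for (int j = 1; j < I - 1; ++j)
        for (int i = 1; i < I - 1; ++i) {
          R_xlen_t q = idx3(i, j, k, I);
          double s = rr[q] +
              ih2 * (zz[q - 1] + zz[q - I] + zz[q - II]);
          zz[q] = s * idic[q];
        }
    for (int k = I - 2; k >= 1; --k)
      for (int j = I - 2; j >= 1; --j)
        for (int i = I - 2; i >= 1; --i) {
          R_xlen_t q = idx3(i, j, k, I);
          zz[q] += ih2 * (zz[q + 1] + zz[q + I] + zz[q + II]) * idic[q];
        }
  };

  auto matvec = [&](const std::vector<double>& in, std::vector<double>& out) {
    const double* pin = in.data();
    double* pout = out.data();
    for (int k = 1; k < I - 1; ++k)
      for (int j = 1; j < I - 1; ++j) {
        R_xlen_t row = (R_xlen_t) I * j + II * k;
        const double* d0 = diag.data() + row;
        for (int i = 1; i < I - 1; ++i) {
          R_xlen_t q = row + i;
          pout[q] = d0[i] * pin[q] -
              ih2 * (pin[q - 1] + pin[q + 1] + pin[q - I] + pin[q + I] +
                     pin[q - II] + pin[q + II]);
        }
      }
  };

  // r = b - A u
  matvec(u, Ap);
  for (R_xlen_t q = 0; q < ntot; ++q) r[q] = b[q] - Ap[q];
  apply_precond(r, z);
  double rz = 0.0;
  for (R_xlen_t q = 0; q < ntot; ++q) { p[q] = z[q]; rz += r[q] * z[q]; }

  int it = 0;
  double relres = 0.0;
  for (; it < maxit; ++it) {
    double rr2 = 0.0;
    for (R_xlen_t q = 0; q < ntot; ++q) rr2 += r[q] * r[q];
    relres = std::sqrt(rr2) / bnorm;
    if (relres <= tol) break;

    matvec(p, Ap);
    double pAp = 0.0;
    for (R_xlen_t q = 0; q < ntot; ++q) pAp += p[q] * Ap[q];
    double alpha_cg = rz / pAp;
    for (R_xlen_t q = 0; q < ntot; ++q) {
      u[q] += alpha_cg * p[q];
      r[q] -= alpha_cg * Ap[q];
    }
    apply_precond(r, z);
    double rznew = 0.0;
    for (R_xlen_t q = 0; q < ntot; ++q) rznew += r[q] * z[q];
    double beta = rznew / rz;
    rz = rznew;
    for (R_xlen_t q = 0; q < ntot; ++q) p[q] = z[q] + beta * p[q];
  }

  NumericVector c(ntot);
  for (int k = 0; k < I; ++k)
    for (int j = 0; j < I; ++j)
      for (int i = 0; i < I; ++i) {
        R_xlen_t q = idx3(i, j, k, I);
        bool boundary = (i == 0 || j == 0 || k == 0 ||
                         i == I - 1 || j == I - 1 || k == I - 1);
        c[q] = boundary ? 1.0 : u[q];
      }
  c.attr("dim") = IntegerVector::create(I, I, I);
  return List::create(_["c"] = c, _["iterations"] = it, _["relres"] = relres,
                      _["converged"] = relres <= tol);
}
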