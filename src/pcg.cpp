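// Jacobi-preconditioned conjugate gradients for the 7-point finite-volume
// stencil.  The operator acts on interior voxels only; Dirichlet voxels are
// eliminated (their contribution is pre-folded into the rhs), so entries of
// x at non-interior voxels stay zero throughout.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void stencil_apply(const IntegerVector& dims,
                          const NumericVector& diag,
                          const NumericVector& tx,
                          const NumericVector& ty,
                          const NumericVector& tz,
                          const IntegerVector& interior,
                          const std::vector<double>& x,
                          std::vector<double>& y) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t sx = 1, sy = n1, sz = (R_xlen_t)n1 * n2;
  R_xlen_t v = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++v) {
        if (!interior[v]) { y[v] = 0.0; continue; }
        double acc = diag[v] * x[v];
        // neighbours are in-array for interior voxels (outer shell is
        // Dirichlet by construction); guard anyway
        if (i + 1 < n1) acc -= tx[v] * x[v + sx];
        if (i > 0)      acc -= tx[v - sx] * x[v - sx];
        if (j + 1 < n2) acc -= ty[v] * x[v + sy];
        if (j > 0)      acc -= ty[v - sy] * x[v - sy];
        if (k + 1 < n3) acc -= tz[v] * x[v + sz];
        if (k > 0)      acc -= tz[v - sz] * x[v - sz];
        y[v] = acc;
      }
}

// [[Rcpp::export]]
List pcg_stencil(IntegerVector dims, NumericVector diag, NumericVector tx,
                 NumericVector ty, NumericVector tz, NumericVector rhs,
                 IntegerVector interior, double tol, int maxit) {
  const R_xlen_t n = diag.size();
  std::vector<double> x(n, 0.0), r(n, 0.0), z(n, 0.0), p(n, 0.0), Ap(n, 0.0);
  double bnorm2 = 0.0;
  for (R_xlen_t v = 0; v < n; ++v)
    if (interior[v]) { r[v] = rhs[v]; bnorm2 += rhs[v] * rhs[v]; }
  const double bnorm = std::sqrt(bnorm2);
  if (bnorm == 0.0) {
    return List::create(_["x"] = NumericVector(n), _["residual"] = 0.0,
                        _["iterations"] = 0);
  }
  double rz = 0.0;
  for (R_xlen_t v = 0; v < n; ++v)
    if (interior[v]) { z[v] = r[v] / diag[v]; p[v] = z[v]; rz += r[v] * z[v]; }
  double resid = 1.0;
  int it = 0;
  for (; it < maxit; ++it) {
    stencil_apply(dims, diag, tx, ty, tz, interior, p, Ap);
    double pAp = 0.0;
    for (R_xlen_t v = 0; v < n; ++v) if (interior[v]) pAp += p[v] * Ap[v];
    if (pAp <= 0.0) break;
    const double alpha = rz / pAp;
    double rnorm2 = 0.0;
    for (R_xlen_t v = 0; v < n; ++v)
      if (interior[v]) {
        x[v] += alpha * p[v];
        r[v] -= alpha * Ap[v];
        rnorm2 += r[v] * r[v];
      }
    resid = std::sqrt(rnorm2) / bnorm;
    if (resid <= tol) { ++it; break; }
    double rz_new = 0.0;
    for (R_xlen_t v = 0; v < n; ++v)
      if (interior[v]) { z[v] = r[v] / diag[v]; rz_new += r[v] * z[v]; }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t v = 0; v < n; ++v)
      if (interior[v]) p[v] = z[v] + beta * p[v];
  }
  NumericVector xout(n);
  for (R_xlen_t v = 0; v < n; ++v) xout[v] = x[v];
  return List::create(_["x"] = xout, _["residual"] = resid,
                      _["iterations"] = it);
}
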