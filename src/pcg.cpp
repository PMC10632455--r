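#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Jacobi-preconditioned conjugate gradient for a symmetric positive-definite
// sparse system in dgCMatrix (compressed sparse column) layout. Fully
// sequential and allocation-stable, so repeated solves with identical inputs
// are bit-identical.
//
// [[Rcpp::export(name = ".pcg_jacobi")]]
List pcg_jacobi(S4 A, NumericVector b, double tol, int maxit) {
  IntegerVector Ap = A.slot("p");
  IntegerVector Ai = A.slot("i");
  NumericVector Ax = A.slot("x");
  const int n = b.size();

  std::vector<double> diag(n, 0.0);
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] == j) diag[j] = Ax[k];
  for (int j = 0; j < n; ++j)
    if (diag[j] <= 0.0)
      stop("system matrix has a non-positive diagonal entry");

  std::vector<double> x(n, 0.0), r(n), z(n), p(n), q(n);
  double bnorm = 0.0;
  for (int j = 0; j < n; ++j) bnorm += b[j] * b[j];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["x"] = NumericVector(n), _["iterations"] = 0,
                        _["relres"] = 0.0, _["converged"] = true);
  }

  for (int j = 0; j < n; ++j) r[j] = b[j];            // x0 = 0
  double rz = 0.0;
  for (int j = 0; j < n; ++j) {
    z[j] = r[j] / diag[j];
    p[j] = z[j];
    rz += r[j] * z[j];
  }

  double relres = 1.0;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    // q = A p (column-major scatter)
    std::fill(q.begin(), q.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double pj = p[j];
      if (pj == 0.0) continue;
      for (int k = Ap[j]; k < Ap[j + 1]; ++k) q[Ai[k]] += Ax[k] * pj;
    }
    double pq = 0.0;
    for (int j = 0; j < n; ++j) pq += p[j] * q[j];
    if (pq <= 0.0) stop("conjugate gradient breakdown: matrix not positive definite");
    const double alpha = rz / pq;
    double rnorm = 0.0;
    for (int j = 0; j < n; ++j) {
      x[j] += alpha * p[j];
      r[j] -= alpha * q[j];
      rnorm += r[j] * r[j];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres <= tol) { ++it; break; }
    double rz_new = 0.0;
    for (int j = 0; j < n; ++j) {
      z[j] = r[j] / diag[j];
      rz_new += r[j] * z[j];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int j = 0; j < n; ++j) p[j] = z[j] + beta * p[j];
  }

  NumericVector xout(x.begin(), x.end());
  return List::create(_["x"] = xout, _["iterations"] = it,
                      _["relres"] = relres, _["converged"] = relres <= tol);
}
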