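#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Symmetric matvec with the lower triangle stored in CSR
// (rp: 0-based row pointers, ci: 0-based sorted column indices incl. diagonal).
static void symv(const IntegerVector& rp, const IntegerVector& ci,
                 const NumericVector& ax, const double* x, double* y, int n) {
  for (int i = 0; i < n; ++i) y[i] = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int p = rp[i]; p < rp[i + 1]; ++p) {
      int j = ci[p];
      double a = ax[p];
      y[i] += a * x[j];
      if (j != i) y[j] += a * x[i];
    }
  }
}

// Conjugate gradient with zero-fill incomplete Cholesky preconditioning for
// SPD systems given as the lower triangle in CSR. Returns the solution,
// iteration count, and final relative residual.
// [[Rcpp::export(name = ".pcg_ic0")]]
List pcg_ic0(IntegerVector rp, IntegerVector ci, NumericVector ax,
             NumericVector b, NumericVector x0, double tol, int maxit) {
  const int n = b.size();
  NumericVector lx = clone(ax);
  std::vector<int> diagp(n, -1);
  for (int i = 0; i < n; ++i)
    for (int p = rp[i]; p < rp[i + 1]; ++p)
      if (ci[p] == i) diagp[i] = p;

  // IC(0): rows processed in order, columns sorted ascending within a row
  for (int i = 0; i < n; ++i) {
    for (int p = rp[i]; p < rp[i + 1]; ++p) {
      int j = ci[p];
      double s = ax[p];
      int pi = rp[i], pj = rp[j];
      while (pi < rp[i + 1] && pj < rp[j + 1]) {
        int a = ci[pi], c = ci[pj];
        if (a >= j || c >= j) break;
        if (a == c) { s -= lx[pi] * lx[pj]; ++pi; ++pj; }
        else if (a < c) ++pi;
        else ++pj;
      }
      if (j == i) {
        if (s <= 0) s = ax[p] > 0 ? ax[p] : 1e-300;  // breakdown guard
        lx[p] = std::sqrt(s);
      } else {
        lx[p] = s / lx[diagp[j]];
      }
    }
  }

  std::vector<double> x(x0.begin(), x0.end()), r(n), z(n), pv(n), Ap(n);
  symv(rp, ci, ax, x.data(), Ap.data(), n);
  double bn = 0;
  for (int i = 0; i < n; ++i) { r[i] = b[i] - Ap[i]; bn += b[i] * b[i]; }
  bn = std::sqrt(bn);
  if (bn == 0) bn = 1;

  auto prec = [&](const std::vector<double>& rr, std::vector<double>& zz) {
    for (int i = 0; i < n; ++i) {
      double s = rr[i];
      for (int p = rp[i]; p < rp[i + 1]; ++p) {
        int j = ci[p];
        if (j < i) s -= lx[p] * zz[j];
      }
      zz[i] = s / lx[diagp[i]];
    }
    for (int i = n - 1; i >= 0; --i) {
      double s = zz[i] / lx[diagp[i]];
      zz[i] = s;
      for (int p = rp[i]; p < rp[i + 1]; ++p) {
        int j = ci[p];
        if (j < i) zz[j] -= lx[p] * s;
      }
    }
  };

  prec(r, z);
  double rz = 0;
  for (int i = 0; i < n; ++i) rz += r[i] * z[i];
  for (int i = 0; i < n; ++i) pv[i] = z[i];
  int it = 0;
  double relres = 0;
  for (it = 0; it < maxit; ++it) {
    double rn = 0;
    for (int i = 0; i < n; ++i) rn += r[i] * r[i];
    relres = std::sqrt(rn) / bn;
    if (relres < tol) break;
    symv(rp, ci, ax, pv.data(), Ap.data(), n);
    double pAp = 0;
    for (int i = 0; i < n; ++i) pAp += pv[i] * Ap[i];
    if (pAp <= 0) break;  // loss of positive definiteness: give up
    double alpha = rz / pAp;
    for (int i = 0; i < n; ++i) { x[i] += alpha * pv[i]; r[i] -= alpha * Ap[i]; }
    prec(r, z);
    double rz2 = 0;
    for (int i = 0; i < n; ++i) rz2 += r[i] * z[i];
    double beta = rz2 / rz;
    rz = rz2;
    for (int i = 0; i < n; ++i) pv[i] = z[i] + beta * pv[i];
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iter"] = it, _["relres"] = relres);
}

// y[idx[t]] += w[t] for 1-based idx; used for fast per-voxel accumulation
// of face quantities (diagonal assembly, face-to-voxel field averaging).
// [[Rcpp::export(name = ".scatter_add")]]
NumericVector scatter_add(IntegerVector idx, NumericVector w, int n) {
  NumericVector y(n);
  const int m = idx.size();
  for (int t = 0; t < m; ++t) y[idx[t] - 1] += w[t];
  return y;
}
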