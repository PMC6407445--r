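#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Incomplete-Cholesky preconditioned conjugate gradient for the 7-point
// finite-volume Laplacian on a regular grid.
//
// Voxels are indexed i + nx*(j + ny*k) (column-major, matching R arrays).
// gx/gy/gz hold face conductances (siemens) between voxel (i,j,k) and its
// +x/+y/+z neighbour; a zero face carries no current (natural Neumann).
// mask: 0 = free unknown, 1 = Dirichlet (value in dirval), 2 = excluded
// (zero-conductivity interior, no equation). The outer boundary has no
// faces, i.e. zero-flux.
//
// Preconditioner: ICCG(0) in its stencil form M = (E + F) E^-1 (E + F^T),
// with F the strictly-lower off-diagonal part of A and E diagonal.

// [[Rcpp::export(name = ".cg_laplace")]]
List cg_laplace(IntegerVector dims,
                NumericVector gx, NumericVector gy, NumericVector gz,
                IntegerVector mask, NumericVector dirval,
                double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<int> msk(mask.begin(), mask.end());

  // per-voxel free-free neighbour conductances (zero if the neighbour is
  // not a free unknown), diagonal and right-hand side
  std::vector<double> gxm(N, 0.0), gxp(N, 0.0), gym(N, 0.0), gyp(N, 0.0),
      gzm(N, 0.0), gzp(N, 0.0), diag(N, 0.0), b(N, 0.0);
  auto face = [&](R_xlen_t a, R_xlen_t bb, double g,
                  std::vector<double>& gplus, std::vector<double>& gminus) {
    if (g <= 0.0) return;
    const int ma = msk[a], mb = msk[bb];
    if (ma == 2 || mb == 2) return;
    if (ma == 0) {
      diag[a] += g;
      if (mb == 1) b[a] += g * dirval[bb];
      else gplus[a] = g;
    }
    if (mb == 0) {
      diag[bb] += g;
      if (ma == 1) b[bb] += g * dirval[a];
      else gminus[bb] = g;
    }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        R_xlen_t a = i + sy * j + sz * k;
        face(a, a + sx, gx[i + (R_xlen_t)(nx - 1) * (j + (R_xlen_t)ny * k)],
             gxp, gxm);
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t a = i + sy * j + sz * k;
        face(a, a + sy, gy[i + (R_xlen_t)nx * (j + (R_xlen_t)(ny - 1) * k)],
             gyp, gym);
      }
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t a = i + sy * j + sz * k;
        face(a, a + sz, gz[a], gzp, gzm);
      }

  // free voxels whose every face conductance vanished are electrically
  // isolated: exclude them rather than leaving a singular row
  std::vector<R_xlen_t> freev;
  freev.reserve(N / 2);
  for (R_xlen_t q = 0; q < N; ++q) {
    if (msk[q] == 0) {
      if (diag[q] > 0.0) freev.push_back(q);
      else msk[q] = 2;
    }
  }

  NumericVector xout(N);
  for (R_xlen_t q = 0; q < N; ++q)
    xout[q] = (msk[q] == 1) ? dirval[q] : (msk[q] == 2 ? NA_REAL : 0.0);

  auto finish = [&](std::vector<double>* x, int it, double relres) {
    if (x) for (size_t q = 0; q < freev.size(); ++q)
      xout[freev[q]] = (*x)[freev[q]];
    return List::create(_["values"] = xout, _["iterations"] = it,
                        _["relres"] = relres, _["excluded_mask"] = wrap(msk));
  };
  if (freev.empty()) return finish(nullptr, 0, 0.0);

  double bnorm2 = 0.0;
  for (size_t q = 0; q < freev.size(); ++q) bnorm2 += b[freev[q]] * b[freev[q]];
  const double bnorm = std::sqrt(bnorm2);
  if (bnorm == 0.0) return finish(nullptr, 0, 0.0);

  // ICCG(0) pivots: e_i = a_ii - sum_{lower j} a_ij^2 / e_j
  std::vector<double> e(N, 1.0);
  for (size_t q = 0; q < freev.size(); ++q) {
    const R_xlen_t a = freev[q];
    double v = diag[a];
    if (gxm[a] > 0) v -= gxm[a] * gxm[a] / e[a - sx];
    if (gym[a] > 0) v -= gym[a] * gym[a] / e[a - sy];
    if (gzm[a] > 0) v -= gzm[a] * gzm[a] / e[a - sz];
    e[a] = (v > 1e-12 * diag[a]) ? v : diag[a];
  }

  std::vector<double> x(N, 0.0), r(N, 0.0), z(N, 0.0), p(N, 0.0), Ap(N, 0.0),
      w(N, 0.0);
  auto apply_A = [&](const std::vector<double>& v, std::vector<double>& y) {
    for (size_t q = 0; q < freev.size(); ++q) {
      const R_xlen_t a = freev[q];
      double acc = diag[a] * v[a];
      if (gxm[a] > 0) acc -= gxm[a] * v[a - sx];
      if (gxp[a] > 0) acc -= gxp[a] * v[a + sx];
      if (gym[a] > 0) acc -= gym[a] * v[a - sy];
      if (gyp[a] > 0) acc -= gyp[a] * v[a + sy];
      if (gzm[a] > 0) acc -= gzm[a] * v[a - sz];
      if (gzp[a] > 0) acc -= gzp[a] * v[a + sz];
      y[a] = acc;
    }
  };
  auto precond = [&](const std::vector<double>& rr, std::vector<double>& zz) {
    // forward: (E + F) w = r (freev is in ascending lexicographic order)
    for (size_t q = 0; q < freev.size(); ++q) {
      const R_xlen_t a = freev[q];
      double acc = rr[a];
      if (gxm[a] > 0) acc += gxm[a] * w[a - sx];
      if (gym[a] > 0) acc += gym[a] * w[a - sy];
      if (gzm[a] > 0) acc += gzm[a] * w[a - sz];
      w[a] = acc / e[a];
    }
    // backward: (E + F^T) z = E w  =>  z_i = w_i + (sum_upper g z_j) / e_i
    for (size_t q = freev.size(); q-- > 0;) {
      const R_xlen_t a = freev[q];
      double acc = 0.0;
      if (gxp[a] > 0) acc += gxp[a] * zz[a + sx];
      if (gyp[a] > 0) acc += gyp[a] * zz[a + sy];
      if (gzp[a] > 0) acc += gzp[a] * zz[a + sz];
      zz[a] = w[a] + acc / e[a];
    }
  };

  for (size_t q = 0; q < freev.size(); ++q) r[freev[q]] = b[freev[q]];
  precond(r, z);
  for (size_t q = 0; q < freev.size(); ++q) p[freev[q]] = z[freev[q]];
  double rz = 0.0;
  for (size_t q = 0; q < freev.size(); ++q) rz += r[freev[q]] * z[freev[q]];
  double relres = 1.0;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    apply_A(p, Ap);
    double pAp = 0.0;
    for (size_t q = 0; q < freev.size(); ++q)
      pAp += p[freev[q]] * Ap[freev[q]];
    if (pAp <= 0.0) break;
    const double alpha = rz / pAp;
    double rn2 = 0.0;
    for (size_t q = 0; q < freev.size(); ++q) {
      const R_xlen_t a = freev[q];
      x[a] += alpha * p[a];
      r[a] -= alpha * Ap[a];
      rn2 += r[a] * r[a];
    }
    relres = std::sqrt(rn2) / bnorm;
    if (relres <= tol) { ++it; break; }
    precond(r, z);
    double rz_new = 0.0;
    for (size_t q = 0; q < freev.size(); ++q)
      rz_new += r[freev[q]] * z[freev[q]];
    const double beta = rz_new / rz;
    rz = rz_new;
    for (size_t q = 0; q < freev.size(); ++q) {
      const R_xlen_t a = freev[q];
      p[a] = z[a] + beta * p[a];
    }
  }
  return finish(&x, it, relres);
}
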