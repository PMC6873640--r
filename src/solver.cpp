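#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Matrix-free cell-centred finite-volume operator for -div(sigma grad u) on a
// voxel grid. The isotropic part uses harmonic-mean face conductances
// (Fx/Fy/Fz, in siemens, already scaled by the voxel edge length). The
// anisotropic remainder (sigma_l - sigma_t) f f^T, present only in
// myocardium, is discretised as h^3 * D^T M D with D the masked
// central-difference gradient (one-sided at domain boundaries), which keeps
// the operator symmetric positive semi-definite by construction.
//
// Layout: linear index i = x + nx*(y + ny*z), matching R's column-major
// array order. All distances are in metres, conductivities in S/m,
// potentials in volts; operator output is a current (amperes).

struct Grid {
  int nx, ny, nz;
  R_xlen_t N;
  Grid(IntegerVector dim) : nx(dim[0]), ny(dim[1]), nz(dim[2]) {
    N = (R_xlen_t)nx * ny * nz;
  }
};

// Gradient coefficients along one axis at cell i:
//   g = cp*u[i+s] + cs*u[i] + cm*u[i-s]
// using only in-domain neighbours; zero if the cell has none on this axis.
static inline void axis_coef(bool hp, bool hm, double h,
                             double &cp, double &cs, double &cm) {
  if (hp && hm)      { cp = 0.5 / h; cs = 0.0;      cm = -0.5 / h; }
  else if (hp)       { cp = 1.0 / h; cs = -1.0 / h; cm = 0.0;      }
  else if (hm)       { cp = 0.0;     cs = 1.0 / h;  cm = -1.0 / h; }
  else               { cp = 0.0;     cs = 0.0;      cm = 0.0;      }
}

// y = A u. M is either length 6N (columns Mxx,Myy,Mzz,Mxy,Mxz,Myz, each of
// length N) or length 0. diag_add (length N or 0) adds a lumped diagonal
// term (used for the implicit parabolic step of the bidomain solve).
// work: 3N doubles of scratch for the anisotropic fluxes.
static void apply_op(const Grid &g, double h,
                     const double *Fx, const double *Fy, const double *Fz,
                     const double *M, bool hasM,
                     const int *dom,
                     const double *diag_add, bool hasDiag,
                     const double *u, double *y, double *work) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const R_xlen_t N = g.N;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  // isotropic part: sum of face conductances times potential differences
  for (R_xlen_t i = 0; i < N; ++i) y[i] = 0.0;
  for (int z = 0; z < nz; ++z) {
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = sy * yy + sz * z;
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = base + x;
        if (!dom[i]) continue;
        double acc = 0.0;
        double ui = u[i];
        if (x + 1 < nx && Fx[i] != 0.0) acc += Fx[i] * (ui - u[i + sx]);
        if (x > 0 && Fx[i - sx] != 0.0) acc += Fx[i - sx] * (ui - u[i - sx]);
        if (yy + 1 < ny && Fy[i] != 0.0) acc += Fy[i] * (ui - u[i + sy]);
        if (yy > 0 && Fy[i - sy] != 0.0) acc += Fy[i - sy] * (ui - u[i - sy]);
        if (z + 1 < nz && Fz[i] != 0.0) acc += Fz[i] * (ui - u[i + sz]);
        if (z > 0 && Fz[i - sz] != 0.0) acc += Fz[i - sz] * (ui - u[i - sz]);
        if (hasDiag) acc += diag_add[i] * ui;
        y[i] = acc;
      }
    }
  }
  if (!hasM) return;

  const double *Mxx = M, *Myy = M + N, *Mzz = M + 2 * N;
  const double *Mxy = M + 3 * N, *Mxz = M + 4 * N, *Myz = M + 5 * N;
  double *f1 = work, *f2 = work + N, *f3 = work + 2 * N;
  for (R_xlen_t i = 0; i < 3 * N; ++i) work[i] = 0.0;

  // anisotropic fluxes f = M * grad(u), only where M is non-zero
  for (int z = 0; z < nz; ++z) {
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = sy * yy + sz * z;
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = base + x;
        if (Mxx[i] == 0.0 && Myy[i] == 0.0 && Mzz[i] == 0.0) continue;
        bool hpx = (x + 1 < nx) && dom[i + sx], hmx = (x > 0) && dom[i - sx];
        bool hpy = (yy + 1 < ny) && dom[i + sy], hmy = (yy > 0) && dom[i - sy];
        bool hpz = (z + 1 < nz) && dom[i + sz], hmz = (z > 0) && dom[i - sz];
        double cp, cs, cm, g1 = 0, g2 = 0, g3 = 0;
        axis_coef(hpx, hmx, h, cp, cs, cm);
        g1 = cp * (hpx ? u[i + sx] : 0.0) + cs * u[i] + cm * (hmx ? u[i - sx] : 0.0);
        axis_coef(hpy, hmy, h, cp, cs, cm);
        g2 = cp * (hpy ? u[i + sy] : 0.0) + cs * u[i] + cm * (hmy ? u[i - sy] : 0.0);
        axis_coef(hpz, hmz, h, cp, cs, cm);
        g3 = cp * (hpz ? u[i + sz] : 0.0) + cs * u[i] + cm * (hmz ? u[i - sz] : 0.0);
        f1[i] = Mxx[i] * g1 + Mxy[i] * g2 + Mxz[i] * g3;
        f2[i] = Mxy[i] * g1 + Myy[i] * g2 + Myz[i] * g3;
        f3[i] = Mxz[i] * g1 + Myz[i] * g2 + Mzz[i] * g3;
      }
    }
  }

  // y += h^3 * D^T f  (exact transpose of the gradient used above)
  const double h3 = h * h * h;
  for (int z = 0; z < nz; ++z) {
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = sy * yy + sz * z;
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = base + x;
        if (!dom[i]) continue;
        double acc = 0.0;
        // own row's self coefficients
        bool hpx = (x + 1 < nx) && dom[i + sx], hmx = (x > 0) && dom[i - sx];
        bool hpy = (yy + 1 < ny) && dom[i + sy], hmy = (yy > 0) && dom[i - sy];
        bool hpz = (z + 1 < nz) && dom[i + sz], hmz = (z > 0) && dom[i - sz];
        double cp, cs, cm;
        if (f1[i] != 0.0 || f2[i] != 0.0 || f3[i] != 0.0) {
          axis_coef(hpx, hmx, h, cp, cs, cm); acc += cs * f1[i];
          axis_coef(hpy, hmy, h, cp, cs, cm); acc += cs * f2[i];
          axis_coef(hpz, hmz, h, cp, cs, cm); acc += cs * f3[i];
        }
        // neighbour rows referencing u[i]:
        // row i+s uses u[i] with its minus coefficient, row i-s with its plus
        if (x + 1 < nx) { R_xlen_t c = i + sx; if (f1[c] != 0.0) {
          bool chp = (x + 2 < nx) && dom[c + sx];
          acc += (chp ? -0.5 / h : -1.0 / h) * f1[c]; } }
        if (x > 0) { R_xlen_t c = i - sx; if (f1[c] != 0.0) {
          bool chm = (x - 2 >= 0) && dom[c - sx];
          acc += (chm ? 0.5 / h : 1.0 / h) * f1[c]; } }
        if (yy + 1 < ny) { R_xlen_t c = i + sy; if (f2[c] != 0.0) {
          bool chp = (yy + 2 < ny) && dom[c + sy];
          acc += (chp ? -0.5 / h : -1.0 / h) * f2[c]; } }
        if (yy > 0) { R_xlen_t c = i - sy; if (f2[c] != 0.0) {
          bool chm = (yy - 2 >= 0) && dom[c - sy];
          acc += (chm ? 0.5 / h : 1.0 / h) * f2[c]; } }
        if (z + 1 < nz) { R_xlen_t c = i + sz; if (f3[c] != 0.0) {
          bool chp = (z + 2 < nz) && dom[c + sz];
          acc += (chp ? -0.5 / h : -1.0 / h) * f3[c]; } }
        if (z > 0) { R_xlen_t c = i - sz; if (f3[c] != 0.0) {
          bool chm = (z - 2 >= 0) && dom[c - sz];
          acc += (chm ? 0.5 / h : 1.0 / h) * f3[c]; } }
        y[i] += h3 * acc;
      }
    }
  }
}

// Exact diagonal of the operator (for Jacobi preconditioning).
static void op_diag(const Grid &g, double h,
                    const double *Fx, const double *Fy, const double *Fz,
                    const double *M, bool hasM,
                    const int *dom,
                    const double *diag_add, bool hasDiag,
                    double *d) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const R_xlen_t N = g.N;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double h3 = h * h * h;
  const double *Mxx = 0, *Myy = 0, *Mzz = 0, *Mxy = 0, *Mxz = 0, *Myz = 0;
  if (hasM) {
    Mxx = M; Myy = M + N; Mzz = M + 2 * N;
    Mxy = M + 3 * N; Mxz = M + 4 * N; Myz = M + 5 * N;
  }
  for (int z = 0; z < nz; ++z) {
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = sy * yy + sz * z;
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = base + x;
        d[i] = 0.0;
        if (!dom[i]) continue;
        double acc = 0.0;
        if (x + 1 < nx) acc += Fx[i];
        if (x > 0) acc += Fx[i - sx];
        if (yy + 1 < ny) acc += Fy[i];
        if (yy > 0) acc += Fy[i - sy];
        if (z + 1 < nz) acc += Fz[i];
        if (z > 0) acc += Fz[i - sz];
        if (hasDiag) acc += diag_add[i];
        if (hasM) {
          bool hpx = (x + 1 < nx) && dom[i + sx], hmx = (x > 0) && dom[i - sx];
          bool hpy = (yy + 1 < ny) && dom[i + sy], hmy = (yy > 0) && dom[i - sy];
          bool hpz = (z + 1 < nz) && dom[i + sz], hmz = (z > 0) && dom[i - sz];
          double cp, cs1, cs2, cs3, cm;
          axis_coef(hpx, hmx, h, cp, cs1, cm);
          axis_coef(hpy, hmy, h, cp, cs2, cm);
          axis_coef(hpz, hmz, h, cp, cs3, cm);
          // self-row quadratic form a_s' M a_s (PSD, zero for central cells)
          double self = cs1 * cs1 * Mxx[i] + cs2 * cs2 * Myy[i] + cs3 * cs3 * Mzz[i]
            + 2.0 * (cs1 * cs2 * Mxy[i] + cs1 * cs3 * Mxz[i] + cs2 * cs3 * Myz[i]);
          acc += h3 * self;
          // neighbour rows: row i+s references u[i] with its minus coefficient
          if (x + 1 < nx && Mxx[i + sx] != 0.0) {
            bool chp = (x + 2 < nx) && dom[i + 2 * sx];
            double c = chp ? -0.5 / h : -1.0 / h;
            acc += h3 * c * c * Mxx[i + sx];
          }
          if (x > 0 && Mxx[i - sx] != 0.0) {
            bool chm = (x - 2 >= 0) && dom[i - 2 * sx];
            double c = chm ? 0.5 / h : 1.0 / h;
            acc += h3 * c * c * Mxx[i - sx];
          }
          if (yy + 1 < ny && Myy[i + sy] != 0.0) {
            bool chp = (yy + 2 < ny) && dom[i + 2 * sy];
            double c = chp ? -0.5 / h : -1.0 / h;
            acc += h3 * c * c * Myy[i + sy];
          }
          if (yy > 0 && Myy[i - sy] != 0.0) {
            bool chm = (yy - 2 >= 0) && dom[i - 2 * sy];
            double c = chm ? 0.5 / h : 1.0 / h;
            acc += h3 * c * c * Myy[i - sy];
          }
          if (z + 1 < nz && Mzz[i + sz] != 0.0) {
            bool chp = (z + 2 < nz) && dom[i + 2 * sz];
            double c = chp ? -0.5 / h : -1.0 / h;
            acc += h3 * c * c * Mzz[i + sz];
          }
          if (z > 0 && Mzz[i - sz] != 0.0) {
            bool chm = (z - 2 >= 0) && dom[i - 2 * sz];
            double c = chm ? 0.5 / h : 1.0 / h;
            acc += h3 * c * c * Mzz[i - sz];
          }
        }
        d[i] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_apply_op(IntegerVector dim, double h,
                           NumericVector Fx, NumericVector Fy, NumericVector Fz,
                           NumericVector M, IntegerVector dom,
                           NumericVector diag_add, NumericVector u) {
  Grid g(dim);
  bool hasM = M.size() > 0;
  bool hasDiag = diag_add.size() > 0;
  NumericVector y(g.N);
  std::vector<double> work(hasM ? 3 * g.N : 0);
  apply_op(g, h, REAL(Fx), REAL(Fy), REAL(Fz),
           hasM ? REAL(M) : 0, hasM, INTEGER(dom),
           hasDiag ? REAL(diag_add) : 0, hasDiag,
           REAL(u), REAL(y), work.data());
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_op_diag(IntegerVector dim, double h,
                          NumericVector Fx, NumericVector Fy, NumericVector Fz,
                          NumericVector M, IntegerVector dom,
                          NumericVector diag_add) {
  Grid g(dim);
  bool hasM = M.size() > 0;
  bool hasDiag = diag_add.size() > 0;
  NumericVector d(g.N);
  op_diag(g, h, REAL(Fx), REAL(Fy), REAL(Fz),
          hasM ? REAL(M) : 0, hasM, INTEGER(dom),
          hasDiag ? REAL(diag_add) : 0, hasDiag, REAL(d));
  return d;
}

// Jacobi-preconditioned conjugate gradients with Dirichlet cells held fixed.
// x0 supplies both the initial guess and the Dirichlet values (at fixed_idx,
// 0-based). Convergence: ||r||_2 / ||b_eff||_2 <= tol, with b_eff the
// right-hand side after moving Dirichlet values across.
// [[Rcpp::export]]
List cpp_cg_solve(IntegerVector dim, double h,
                  NumericVector Fx, NumericVector Fy, NumericVector Fz,
                  NumericVector M, IntegerVector dom,
                  NumericVector diag_add,
                  IntegerVector fixed_idx,
                  NumericVector x0, NumericVector b,
                  double tol, int maxit) {
  Grid g(dim);
  const R_xlen_t N = g.N;
  bool hasM = M.size() > 0;
  bool hasDiag = diag_add.size() > 0;
  const double *pM = hasM ? REAL(M) : 0;
  const double *pD = hasDiag ? REAL(diag_add) : 0;
  const int *dm = INTEGER(dom);

  std::vector<int> freec(N, 0);
  for (R_xlen_t i = 0; i < N; ++i) freec[i] = dm[i];
  for (R_xlen_t k = 0; k < fixed_idx.size(); ++k) freec[fixed_idx[k]] = 0;

  std::vector<double> x(REAL(x0), REAL(x0) + N);
  std::vector<double> r(N), z(N), p(N), Ap(N), diag(N);
  std::vector<double> work(hasM ? 3 * N : 0);

  op_diag(g, h, REAL(Fx), REAL(Fy), REAL(Fz), pM, hasM, dm, pD, hasDiag,
          diag.data());

  // effective RHS norm: b - A x_dirichlet, free entries only
  {
    std::vector<double> xd(N, 0.0);
    for (R_xlen_t k = 0; k < fixed_idx.size(); ++k) {
      R_xlen_t i = fixed_idx[k];
      xd[i] = x[i];
    }
    apply_op(g, h, REAL(Fx), REAL(Fy), REAL(Fz), pM, hasM, dm, pD, hasDiag,
             xd.data(), Ap.data(), work.data());
  }
  double bnorm2 = 0.0;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (freec[i]) {
      double v = REAL(b)[i] - Ap[i];
      bnorm2 += v * v;
    }
  }
  double bnorm = std::sqrt(bnorm2);

  apply_op(g, h, REAL(Fx), REAL(Fy), REAL(Fz), pM, hasM, dm, pD, hasDiag,
           x.data(), Ap.data(), work.data());
  double rnorm2 = 0.0;
  for (R_xlen_t i = 0; i < N; ++i) {
    r[i] = freec[i] ? (REAL(b)[i] - Ap[i]) : 0.0;
    rnorm2 += r[i] * r[i];
  }

  int iters = 0;
  double relres = (bnorm > 0.0) ? std::sqrt(rnorm2) / bnorm : 0.0;
  if (bnorm == 0.0) {
    // homogeneous effective RHS: the free part of the solution is zero
    for (R_xlen_t i = 0; i < N; ++i) if (freec[i]) x[i] = 0.0;
  }
  if (relres > tol && bnorm > 0.0) {
    double rz = 0.0;
    for (R_xlen_t i = 0; i < N; ++i) {
      z[i] = (freec[i] && diag[i] > 0.0) ? r[i] / diag[i] : 0.0;
      rz += r[i] * z[i];
      p[i] = z[i];
    }
    for (iters = 1; iters <= maxit; ++iters) {
      apply_op(g, h, REAL(Fx), REAL(Fy), REAL(Fz), pM, hasM, dm, pD, hasDiag,
               p.data(), Ap.data(), work.data());
      double pAp = 0.0;
      for (R_xlen_t i = 0; i < N; ++i) if (freec[i]) pAp += p[i] * Ap[i];
      if (pAp <= 0.0) break;
      double alpha = rz / pAp;
      rnorm2 = 0.0;
      for (R_xlen_t i = 0; i < N; ++i) {
        if (!freec[i]) continue;
        x[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
        rnorm2 += r[i] * r[i];
      }
      relres = std::sqrt(rnorm2) / bnorm;
      if (relres <= tol) break;
      double rz_new = 0.0;
      for (R_xlen_t i = 0; i < N; ++i) {
        z[i] = (freec[i] && diag[i] > 0.0) ? r[i] / diag[i] : 0.0;
        rz_new += r[i] * z[i];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (R_xlen_t i = 0; i < N; ++i) p[i] = z[i] + beta * p[i];
      if (iters % 200 == 0) Rcpp::checkUserInterrupt();
    }
    if (iters > maxit) iters = maxit;
  }

  NumericVector xout(N);
  for (R_xlen_t i = 0; i < N; ++i) xout[i] = x[i];
  return List::create(_["x"] = xout, _["iterations"] = iters,
                      _["relres"] = relres,
                      _["converged"] = (relres <= tol));
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher) with grid
// weight w (physical spacing along the axis).
static void dt1d(const double *f, double *d, int n, double w,
                 std::vector<int> &v, std::vector<double> &zz) {
  const double INF = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; zz[0] = -INF; zz[1] = INF;
      continue;
    }
    double s = ((f[q] + (double)q * q * w2) -
                (f[v[k]] + (double)v[k] * v[k] * w2)) /
               (2.0 * w2 * (q - v[k]));
    while (s <= zz[k]) {
      --k;
      s = ((f[q] + (double)q * q * w2) -
           (f[v[k]] + (double)v[k] * v[k] * w2)) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    zz[k] = s;
    zz[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < (double)q) ++k;
    int p = v[k];
    d[q] = (double)(q - p) * (q - p) * w2 + f[p];
  }
}

// Euclidean distance (in the units of `spacing`) from every voxel to the
// nearest voxel where mask is TRUE.
// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector dim, LogicalVector mask,
                        NumericVector spacing) {
  Grid g(dim);
  const R_xlen_t N = g.N;
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(N);
  for (R_xlen_t i = 0; i < N; ++i) d[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zz(nmax + 1);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = sy * y + sz * z;
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f.data(), out.data(), nx, spacing[0], v, zz);
      for (int x = 0; x < nx; ++x) d[base + x] = out[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + sz * z;
      for (int y = 0; y < ny; ++y) f[y] = d[base + sy * y];
      dt1d(f.data(), out.data(), ny, spacing[1], v, zz);
      for (int y = 0; y < ny; ++y) d[base + sy * y] = out[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + sy * y;
      for (int z = 0; z < nz; ++z) f[z] = d[base + sz * z];
      dt1d(f.data(), out.data(), nz, spacing[2], v, zz);
      for (int z = 0; z < nz; ++z) d[base + sz * z] = out[z];
    }

  NumericVector res(N);
  for (R_xlen_t i = 0; i < N; ++i)
    res[i] = (d[i] == INF) ? R_PosInf : std::sqrt(d[i]);
  return res;
}

// 6-connected flood fill within mask from seed voxels (0-based indices).
// [[Rcpp::export]]
LogicalVector cpp_flood6(IntegerVector dim, LogicalVector mask,
                         IntegerVector seeds) {
  Grid g(dim);
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  LogicalVector reached(g.N, false);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t k = 0; k < seeds.size(); ++k) {
    R_xlen_t i = seeds[k];
    if (mask[i] && !reached[i]) { reached[i] = true; stack.push_back(i); }
  }
  while (!stack.empty()) {
    R_xlen_t i = stack.back();
    stack.pop_back();
    int x = (int)(i % nx);
    int y = (int)((i / nx) % ny);
    int z = (int)(i / sz);
    R_xlen_t nb[6];
    int nn = 0;
    if (x + 1 < nx) nb[nn++] = i + 1;
    if (x > 0) nb[nn++] = i - 1;
    if (y + 1 < ny) nb[nn++] = i + sy;
    if (y > 0) nb[nn++] = i - sy;
    if (z + 1 < nz) nb[nn++] = i + sz;
    if (z > 0) nb[nn++] = i - sz;
    for (int q = 0; q < nn; ++q) {
      R_xlen_t j = nb[q];
      if (mask[j] && !reached[j]) { reached[j] = true; stack.push_back(j); }
    }
  }
  return reached;
}
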