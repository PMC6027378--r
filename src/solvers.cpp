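// Geometric-multigrid preconditioned Krylov solvers for masked 7-point
// finite-volume operators on uniform voxel grids.
//
// The operator is stored as per-cell arrays: diagonal `d` and the six
// off-diagonal coefficients (aW/aE along x, aS/aN along y, aB/aT along z),
// i.e. row m reads  d[m] x[m] + aW[m] x[m-1] + ... + aT[m] x[m+nx*ny].
// Cells with act[m] == 0 are Dirichlet-eliminated (x fixed at 0); their
// coefficients and any coefficient pointing at them must be assembled as 0.
//
// The hierarchy halves every even dimension >= 4 per level and
// re-discretizes by face-coefficient aggregation (sum of fine face
// coefficients across a coarse face, scaled by h_fine/h_coarse), which
// preserves the M-matrix structure of diffusion/upwind-advection operators.
// Smoother: red-black Gauss-Seidel; the V-cycle is symmetrized (forward
// pre-smoothing, reversed post-smoothing) so it can precondition CG.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Level {
  int nx, ny, nz;
  std::vector<double> d, aW, aE, aS, aN, aB, aT;
  std::vector<unsigned char> act;
  std::vector<double> x, b, r;  // work vectors
  size_t N() const { return (size_t)nx * ny * nz; }
};

struct MG {
  std::vector<Level> lev;
  int npre = 2, npost = 2, ncoarse = 100;
};

static inline size_t idx3(const Level& L, int i, int j, int k) {
  return (size_t)i + (size_t)L.nx * ((size_t)j + (size_t)L.ny * (size_t)k);
}

static void rbgs_color(Level& L, std::vector<double>& x,
                       const std::vector<double>& b, int color) {
  const int nx = L.nx, ny = L.ny, nz = L.nz;
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t row = sy * j + sz * k;
      int par = (j + k + color) & 1;
      // cells with (i+j+k) % 2 == color  =>  i parity = (color - j - k) mod 2
      int i0 = ((2 - par) & 1) ? 1 : 0;  // i starts at (color+j+k)%2 ... compute directly
      i0 = ((color - j - k) % 2 + 2) % 2;
      for (int i = i0; i < nx; i += 2) {
        size_t m = row + i;
        if (!L.act[m]) { x[m] = 0.0; continue; }
        double s = b[m];
        if (i > 0)      s -= L.aW[m] * x[m - 1];
        if (i < nx - 1) s -= L.aE[m] * x[m + 1];
        if (j > 0)      s -= L.aS[m] * x[m - sy];
        if (j < ny - 1) s -= L.aN[m] * x[m + sy];
        if (k > 0)      s -= L.aB[m] * x[m - sz];
        if (k < nz - 1) s -= L.aT[m] * x[m + sz];
        x[m] = s / L.d[m];
      }
    }
}

static void smooth_fwd(Level& L, std::vector<double>& x,
                       const std::vector<double>& b, int sweeps) {
  for (int s = 0; s < sweeps; ++s) {
    rbgs_color(L, x, b, 0);
    rbgs_color(L, x, b, 1);
  }
}

static void smooth_bwd(Level& L, std::vector<double>& x,
                       const std::vector<double>& b, int sweeps) {
  for (int s = 0; s < sweeps; ++s) {
    rbgs_color(L, x, b, 1);
    rbgs_color(L, x, b, 0);
  }
}

static void apply_op(const Level& L, const std::vector<double>& x,
                     std::vector<double>& y) {
  const int nx = L.nx, ny = L.ny, nz = L.nz;
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t m = idx3(L, i, j, k);
        if (!L.act[m]) { y[m] = 0.0; continue; }
        double s = L.d[m] * x[m];
        if (i > 0)      s += L.aW[m] * x[m - 1];
        if (i < nx - 1) s += L.aE[m] * x[m + 1];
        if (j > 0)      s += L.aS[m] * x[m - sy];
        if (j < ny - 1) s += L.aN[m] * x[m + sy];
        if (k > 0)      s += L.aB[m] * x[m - sz];
        if (k < nz - 1) s += L.aT[m] * x[m + sz];
        y[m] = s;
      }
}

static void residual(const Level& L, const std::vector<double>& x,
                     const std::vector<double>& b, std::vector<double>& r) {
  apply_op(L, x, r);
  for (size_t m = 0; m < L.N(); ++m)
    r[m] = L.act[m] ? (b[m] - r[m]) : 0.0;
}

// Build the next-coarser level by face-coefficient aggregation.
static bool coarsen(const Level& F, Level& C) {
  int fx = (F.nx % 2 == 0 && F.nx >= 4) ? 2 : 1;
  int fy = (F.ny % 2 == 0 && F.ny >= 4) ? 2 : 1;
  int fz = (F.nz % 2 == 0 && F.nz >= 4) ? 2 : 1;
  if (fx == 1 && fy == 1 && fz == 1) return false;
  if (F.N() <= 64) return false;
  C.nx = F.nx / fx; C.ny = F.ny / fy; C.nz = F.nz / fz;
  size_t N = C.N();
  C.d.assign(N, 0.0);
  C.aW.assign(N, 0.0); C.aE.assign(N, 0.0);
  C.aS.assign(N, 0.0); C.aN.assign(N, 0.0);
  C.aB.assign(N, 0.0); C.aT.assign(N, 0.0);
  C.act.assign(N, 0);
  C.x.assign(N, 0.0); C.b.assign(N, 0.0); C.r.assign(N, 0.0);
  std::vector<double> sigma(N, 0.0);
  const double scx = (fx == 2) ? 0.5 : 1.0;
  const double scy = (fy == 2) ? 0.5 : 1.0;
  const double scz = (fz == 2) ? 0.5 : 1.0;
  for (int k = 0; k < F.nz; ++k)
    for (int j = 0; j < F.ny; ++j)
      for (int i = 0; i < F.nx; ++i) {
        size_t m = idx3(F, i, j, k);
        if (!F.act[m]) continue;
        int ci = i / fx, cj = j / fy, ck = k / fz;
        size_t cm = idx3(C, ci, cj, ck);
        C.act[cm] = 1;
        sigma[cm] += F.d[m] + F.aW[m] + F.aE[m] + F.aS[m] + F.aN[m] +
                     F.aB[m] + F.aT[m];
        // faces leaving the coarse block contribute to coarse couplings
        if (i > 0      && (i % fx) == 0)      C.aW[cm] += scx * F.aW[m];
        if (i < F.nx-1 && ((i+1) % fx) == 0)  C.aE[cm] += scx * F.aE[m];
        if (j > 0      && (j % fy) == 0)      C.aS[cm] += scy * F.aS[m];
        if (j < F.ny-1 && ((j+1) % fy) == 0)  C.aN[cm] += scy * F.aN[m];
        if (k > 0      && (k % fz) == 0)      C.aB[cm] += scz * F.aB[m];
        if (k < F.nz-1 && ((k+1) % fz) == 0)  C.aT[cm] += scz * F.aT[m];
      }
  for (size_t m = 0; m < N; ++m) {
    if (!C.act[m]) continue;
    C.d[m] = sigma[m] - (C.aW[m] + C.aE[m] + C.aS[m] + C.aN[m] +
                         C.aB[m] + C.aT[m]);
    if (C.d[m] <= 0.0) C.d[m] = 1e-300;  // degenerate guard
  }
  return true;
}

static void restrict_resid(const Level& F, const std::vector<double>& rf,
                           Level& C) {
  int fx = F.nx / C.nx, fy = F.ny / C.ny, fz = F.nz / C.nz;
  std::fill(C.b.begin(), C.b.end(), 0.0);
  for (int k = 0; k < F.nz; ++k)
    for (int j = 0; j < F.ny; ++j)
      for (int i = 0; i < F.nx; ++i) {
        size_t m = idx3(F, i, j, k);
        if (!F.act[m]) continue;
        C.b[idx3(C, i / fx, j / fy, k / fz)] += rf[m];
      }
}

static void prolong_add(Level& F, std::vector<double>& xf, const Level& C) {
  int fx = F.nx / C.nx, fy = F.ny / C.ny, fz = F.nz / C.nz;
  for (int k = 0; k < F.nz; ++k)
    for (int j = 0; j < F.ny; ++j)
      for (int i = 0; i < F.nx; ++i) {
        size_t m = idx3(F, i, j, k);
        if (!F.act[m]) continue;
        xf[m] += C.x[idx3(C, i / fx, j / fy, k / fz)];
      }
}

static void vcycle(MG& mg, size_t l, std::vector<double>& x,
                   const std::vector<double>& b) {
  Level& L = mg.lev[l];
  if (l == mg.lev.size() - 1) {
    for (int s = 0; s < mg.ncoarse; ++s) {
      rbgs_color(L, x, b, 0);
      rbgs_color(L, x, b, 1);
    }
    return;
  }
  smooth_fwd(L, x, b, mg.npre);
  residual(L, x, b, L.r);
  Level& Lc = mg.lev[l + 1];
  restrict_resid(L, L.r, Lc);
  std::fill(Lc.x.begin(), Lc.x.end(), 0.0);
  vcycle(mg, l + 1, Lc.x, Lc.b);
  prolong_add(L, x, Lc);
  smooth_bwd(L, x, b, mg.npost);
}

static void precond(MG& mg, const std::vector<double>& r,
                    std::vector<double>& z) {
  std::fill(z.begin(), z.end(), 0.0);
  Level& L0 = mg.lev[0];
  std::copy(r.begin(), r.end(), L0.b.begin());
  vcycle(mg, 0, z, L0.b);
}

static double dotp(const std::vector<double>& a, const std::vector<double>& b) {
  double s = 0.0;
  for (size_t m = 0; m < a.size(); ++m) s += a[m] * b[m];
  return s;
}

// [[Rcpp::export]]
SEXP mg_setup(IntegerVector dims, NumericVector diag,
              NumericVector aW, NumericVector aE,
              NumericVector aS, NumericVector aN,
              NumericVector aB, NumericVector aT,
              LogicalVector active) {
  MG* mg = new MG();
  Level L;
  L.nx = dims[0]; L.ny = dims[1]; L.nz = dims[2];
  size_t N = L.N();
  if ((size_t)diag.size() != N) stop("coefficient length mismatch");
  L.d.assign(diag.begin(), diag.end());
  L.aW.assign(aW.begin(), aW.end()); L.aE.assign(aE.begin(), aE.end());
  L.aS.assign(aS.begin(), aS.end()); L.aN.assign(aN.begin(), aN.end());
  L.aB.assign(aB.begin(), aB.end()); L.aT.assign(aT.begin(), aT.end());
  L.act.assign(N, 0);
  for (size_t m = 0; m < N; ++m) {
    L.act[m] = active[m] ? 1 : 0;
    if (L.act[m] && !(L.d[m] > 0.0)) stop("nonpositive diagonal on active cell");
  }
  L.x.assign(N, 0.0); L.b.assign(N, 0.0); L.r.assign(N, 0.0);
  mg->lev.push_back(std::move(L));
  while (mg->lev.size() < 20) {
    Level C;
    if (!coarsen(mg->lev.back(), C)) break;
    mg->lev.push_back(std::move(C));
  }
  XPtr<MG> p(mg, true);
  return p;
}

// [[Rcpp::export]]
NumericVector mg_apply(SEXP ptr, NumericVector x) {
  XPtr<MG> mg(ptr);
  Level& L = mg->lev[0];
  std::vector<double> xv(x.begin(), x.end()), yv(L.N());
  apply_op(L, xv, yv);
  return NumericVector(yv.begin(), yv.end());
}

// [[Rcpp::export]]
List mg_solve(SEXP ptr, NumericVector b, NumericVector x0, double tol,
              int maxit, std::string method) {
  XPtr<MG> mg(ptr);
  Level& L = mg->lev[0];
  size_t N = L.N();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> bv(b.begin(), b.end());
  for (size_t m = 0; m < N; ++m)
    if (!L.act[m]) { bv[m] = 0.0; x[m] = 0.0; }
  double bnorm = std::sqrt(dotp(bv, bv));
  if (bnorm == 0.0) {
    return List::create(_["x"] = NumericVector(N, 0.0), _["iter"] = 0,
                        _["relres"] = 0.0, _["converged"] = true);
  }
  std::vector<double> r(N), z(N), p(N), q(N);
  int it = 0;
  double relres = NA_REAL;
  bool conv = false;

  if (method == "mg") {
    // fixed number of V-cycles (no Krylov wrapper); used as a
    // preconditioner application by callers
    for (it = 1; it <= maxit; ++it) {
      residual(L, x, bv, r);
      std::fill(z.begin(), z.end(), 0.0);
      std::copy(r.begin(), r.end(), L.b.begin());
      vcycle(*mg, 0, z, L.b);
      for (size_t m = 0; m < N; ++m) x[m] += z[m];
    }
    residual(L, x, bv, r);
    relres = std::sqrt(dotp(r, r)) / bnorm;
    return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                        _["iter"] = maxit, _["relres"] = relres,
                        _["converged"] = true);
  }

  if (method == "cg") {
    residual(L, x, bv, r);
    relres = std::sqrt(dotp(r, r)) / bnorm;
    if (relres < tol)
      return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                          _["iter"] = 0, _["relres"] = relres,
                          _["converged"] = true);
    precond(*mg, r, z);
    p = z;
    double rz = dotp(r, z);
    for (it = 1; it <= maxit; ++it) {
      apply_op(L, p, q);
      double pq = dotp(p, q);
      if (pq <= 0.0) break;  // loss of positive-definiteness
      double alpha = rz / pq;
      for (size_t m = 0; m < N; ++m) { x[m] += alpha * p[m]; r[m] -= alpha * q[m]; }
      relres = std::sqrt(dotp(r, r)) / bnorm;
      if (relres < tol) { conv = true; break; }
      precond(*mg, r, z);
      double rznew = dotp(r, z);
      double beta = rznew / rz;
      rz = rznew;
      for (size_t m = 0; m < N; ++m) p[m] = z[m] + beta * p[m];
    }
  } else {  // bicgstab (right-preconditioned by one V-cycle)
    std::vector<double> r0(N), v(N), s(N), t(N), ph(N), sh(N);
    residual(L, x, bv, r);
    relres = std::sqrt(dotp(r, r)) / bnorm;
    if (relres < tol)
      return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                          _["iter"] = 0, _["relres"] = relres,
                          _["converged"] = true);
    r0 = r;
    double rho = 1.0, alpha = 1.0, omega = 1.0;
    std::fill(v.begin(), v.end(), 0.0);
    std::fill(p.begin(), p.end(), 0.0);
    for (it = 1; it <= maxit; ++it) {
      double rho1 = dotp(r0, r);
      if (rho1 == 0.0) break;
      if (it == 1) {
        p = r;
      } else {
        double beta = (rho1 / rho) * (alpha / omega);
        for (size_t m = 0; m < N; ++m)
          p[m] = r[m] + beta * (p[m] - omega * v[m]);
      }
      rho = rho1;
      precond(*mg, p, ph);
      apply_op(L, ph, v);
      double r0v = dotp(r0, v);
      if (r0v == 0.0) break;
      alpha = rho / r0v;
      for (size_t m = 0; m < N; ++m) s[m] = r[m] - alpha * v[m];
      double snorm = std::sqrt(dotp(s, s));
      if (snorm / bnorm < tol) {
        for (size_t m = 0; m < N; ++m) x[m] += alpha * ph[m];
        relres = snorm / bnorm;
        conv = true;
        break;
      }
      precond(*mg, s, sh);
      apply_op(L, sh, t);
      double tt = dotp(t, t);
      if (tt == 0.0) break;
      omega = dotp(t, s) / tt;
      for (size_t m = 0; m < N; ++m) {
        x[m] += alpha * ph[m] + omega * sh[m];
        r[m] = s[m] - omega * t[m];
      }
      relres = std::sqrt(dotp(r, r)) / bnorm;
      if (relres < tol) { conv = true; break; }
      if (omega == 0.0) break;
    }
  }
  if (!conv) {  // recompute true residual for the report
    residual(L, x, bv, r);
    relres = std::sqrt(dotp(r, r)) / bnorm;
    conv = relres < tol;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iter"] = it, _["relres"] = relres,
                      _["converged"] = conv);
}

// [[Rcpp::export]]
int mg_levels(SEXP ptr) {
  XPtr<MG> mg(ptr);
  return (int)mg->lev.size();
}
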