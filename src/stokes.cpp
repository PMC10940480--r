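// Steady Stokes flow on a voxel lattice with a staggered (MAC) grid.
//
// Unknowns: face-normal velocities u, v, w (one array per component, same
// dims as the cell grid; face (i,j,k) of component a is the lower face of
// cell (i,j,k) along axis a) and pressure p at fluid cell centres.  Driving
// is a uniform unit body force along the flow axis (plus optional extra
// per-face sources, used by the Picard advection loop).  Boundary conditions
// per axis: periodic, or free-slip symmetry planes at the box faces.
//
// No-slip at solid voxel faces: a face between a fluid and a solid cell
// carries zero normal velocity exactly on the wall plane; a tangential
// neighbour face blocked by solid is treated as a mirror ghost (-u) so the
// wall sits on the cell boundary halfway between the two faces.
//
// Solution: pressure Schur-complement conjugate gradients.  Each outer CG
// iteration applies S = G^T A^{-1} G via an inner Jacobi-preconditioned CG
// solve of the vector Laplacian A (SPD).  The outer relative residual is the
// continuity (divergence) residual; the momentum residual follows from the
// inner solves and is reported separately.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

constexpr int NB_ZERO = -1;   // neighbour value 0, full diagonal weight
constexpr int NB_WALL = -2;   // ghost = -u (wall midway), double diagonal
constexpr int NB_MIRROR = -3; // ghost = +u (symmetry plane), no contribution

struct StokesOp {
  int nx, ny, nz;
  long N;
  double h[3];
  int bc[3]; // 0 periodic, 1 symmetry
  const int* solid;

  std::vector<std::vector<int>> actlist;          // [3] active face indices
  std::vector<std::vector<uint8_t>> act;          // [3] masks
  std::vector<std::array<std::vector<int>, 6>> nb; // [3][6] codes per active face
  std::vector<std::vector<double>> diag;          // [3]
  std::vector<int> fluidcells;
  std::vector<uint8_t> isfluid;

  long idx(int i, int j, int k) const { return i + (long)nx * (j + (long)ny * k); }

  int dim(int a) const { return a == 0 ? nx : (a == 1 ? ny : nz); }

  bool fluid_cell(int i, int j, int k) const {
    // wrap / reflect cell coordinates per bc
    int c[3] = {i, j, k};
    for (int a = 0; a < 3; ++a) {
      int n = dim(a);
      if (c[a] < 0) c[a] = bc[a] == 0 ? c[a] + n : -1 - c[a];
      else if (c[a] >= n) c[a] = bc[a] == 0 ? c[a] - n : 2 * n - 1 - c[a];
    }
    return !solid[idx(c[0], c[1], c[2])];
  }

  void build() {
    isfluid.assign(N, 0);
    for (long q = 0; q < N; ++q) isfluid[q] = solid[q] ? 0 : 1;
    fluidcells.clear();
    for (long q = 0; q < N; ++q) if (isfluid[q]) fluidcells.push_back((int)q);

    act.assign(3, std::vector<uint8_t>(N, 0));
    actlist.assign(3, {});
    nb.assign(3, {});
    diag.assign(3, {});

    for (int a = 0; a < 3; ++a) {
      // activity
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int c[3] = {i, j, k};
            if (bc[a] == 1 && c[a] == 0) continue;   // face on symmetry plane
            int L[3] = {i, j, k};
            L[a] -= 1;
            if (!fluid_cell(L[0], L[1], L[2])) continue;
            if (!isfluid[idx(i, j, k)]) continue;
            act[a][idx(i, j, k)] = 1;
          }
      // stencil for active faces
      for (int s = 0; s < 6; ++s) nb[a][s].clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            long f = idx(i, j, k);
            if (!act[a][f]) continue;
            actlist[a].push_back((int)f);
            int c[3] = {i, j, k};
            double dg = 0.0;
            for (int b = 0; b < 3; ++b) {
              double cb = 1.0 / (h[b] * h[b]);
              for (int sgn = -1; sgn <= 1; sgn += 2) {
                int code;
                int nbc[3] = {c[0], c[1], c[2]};
                nbc[b] += sgn;
                int n = dim(b);
                bool out = nbc[b] < 0 || nbc[b] >= n;
                if (b == a) { // inline
                  if (out) {
                    if (bc[b] == 0) { nbc[b] = (nbc[b] + n) % n; code = (int)idx(nbc[0], nbc[1], nbc[2]); if (!act[a][code]) code = NB_ZERO; }
                    else code = NB_ZERO; // face on the far symmetry plane carries u = 0
                  } else {
                    code = (int)idx(nbc[0], nbc[1], nbc[2]);
                    if (!act[a][code]) code = NB_ZERO;
                  }
                  dg += cb;
                } else {      // tangential
                  if (out) {
                    if (bc[b] == 0) {
                      nbc[b] = (nbc[b] + n) % n;
                      code = (int)idx(nbc[0], nbc[1], nbc[2]);
                      if (!act[a][code]) { code = NB_WALL; dg += 2 * cb; } else dg += cb;
                    } else { code = NB_MIRROR; }
                  } else {
                    code = (int)idx(nbc[0], nbc[1], nbc[2]);
                    if (!act[a][code]) { code = NB_WALL; dg += 2 * cb; } else dg += cb;
                  }
                }
                nb[a][(b << 1) + (sgn > 0 ? 1 : 0)].push_back(code);
              }
            }
            diag[a].push_back(dg);
          }
    }
  }

  // out = A in (negative Laplacian), per component, active faces only
  void applyA(const std::vector<std::vector<double>>& in,
              std::vector<std::vector<double>>& out) const {
    for (int a = 0; a < 3; ++a) {
      const auto& lst = actlist[a];
      const size_t m = lst.size();
      const double* x = in[a].data();
      double* y = out[a].data();
      double cb[6];
      for (int b = 0; b < 3; ++b) { cb[2 * b] = cb[2 * b + 1] = 1.0 / (h[b] * h[b]); }
      for (size_t q = 0; q < m; ++q) {
        double v = diag[a][q] * x[lst[q]];
        for (int s = 0; s < 6; ++s) {
          int code = nb[a][s][q];
          if (code >= 0) v -= cb[s] * x[code];
        }
        y[lst[q]] = v;
      }
    }
  }

  // g = grad p on active faces
  void gradP(const std::vector<double>& p,
             std::vector<std::vector<double>>& g) const {
    for (int a = 0; a < 3; ++a) {
      std::fill(g[a].begin(), g[a].end(), 0.0);
      const auto& lst = actlist[a];
      double inv = 1.0 / h[a];
      for (size_t q = 0; q < lst.size(); ++q) {
        long f = lst[q];
        int k = (int)(f / ((long)nx * ny));
        int rem = (int)(f - (long)k * nx * ny);
        int j = rem / nx, i = rem % nx;
        int L[3] = {i, j, k};
        L[a] -= 1;
        int n = dim(a);
        if (L[a] < 0) L[a] += n;  // active faces with L out of range only occur periodic
        g[a][f] = (p[idx(i, j, k)] - p[idx(L[0], L[1], L[2])]) * inv;
      }
    }
  }

  // div at fluid cells (others zero)
  void divU(const std::vector<std::vector<double>>& uf,
            std::vector<double>& dv) const {
    std::fill(dv.begin(), dv.end(), 0.0);
    for (int cix : fluidcells) {
      long f = cix;
      int k = (int)(f / ((long)nx * ny));
      int rem = (int)(f - (long)k * nx * ny);
      int j = rem / nx, i = rem % nx;
      int c[3] = {i, j, k};
      double s = 0.0;
      for (int a = 0; a < 3; ++a) {
        double lo = uf[a][f];
        int up[3] = {c[0], c[1], c[2]};
        up[a] += 1;
        double hi;
        int n = dim(a);
        if (up[a] >= n) hi = bc[a] == 0 ? uf[a][idx(up[0] - (a==0?n:0), up[1] - (a==1?n:0), up[2] - (a==2?n:0))] : 0.0;
        else hi = uf[a][idx(up[0], up[1], up[2])];
        s += (hi - lo) / h[a];
      }
      dv[f] = s;
    }
  }

  double dot_faces(const std::vector<std::vector<double>>& x,
                   const std::vector<std::vector<double>>& y) const {
    double s = 0.0;
    for (int a = 0; a < 3; ++a)
      for (int f : actlist[a]) s += x[a][f] * y[a][f];
    return s;
  }

  double dot_cells(const std::vector<double>& x, const std::vector<double>& y) const {
    double s = 0.0;
    for (int cix : fluidcells) s += x[cix] * y[cix];
    return s;
  }

  void sub_mean_cells(std::vector<double>& x) const {
    if (fluidcells.empty()) return;
    double m = 0.0;
    for (int cix : fluidcells) m += x[cix];
    m /= (double)fluidcells.size();
    for (int cix : fluidcells) x[cix] -= m;
  }

  // Jacobi-PCG solve of A z = rhs; z overwritten (started from zero).
  // Returns achieved relative residual; iteration count via `iters`.
  double solveA(const std::vector<std::vector<double>>& rhs,
                std::vector<std::vector<double>>& z,
                double rtol, int maxit, int& iters) const {
    std::vector<std::vector<double>> r(3), pd(3), Ap(3), w(3);
    for (int a = 0; a < 3; ++a) {
      r[a] = rhs[a];
      pd[a].assign(N, 0.0); Ap[a].assign(N, 0.0); w[a].assign(N, 0.0);
      std::fill(z[a].begin(), z[a].end(), 0.0);
    }
    double rhsn = std::sqrt(dot_faces(rhs, rhs));
    if (rhsn == 0.0) { iters = 0; return 0.0; }
    auto precond = [&](const std::vector<std::vector<double>>& rr,
                       std::vector<std::vector<double>>& ww) {
      for (int a = 0; a < 3; ++a)
        for (size_t q = 0; q < actlist[a].size(); ++q) {
          int f = actlist[a][q];
          ww[a][f] = rr[a][f] / diag[a][q];
        }
    };
    precond(r, w);
    double rho = dot_faces(r, w);
    for (int a = 0; a < 3; ++a) pd[a] = w[a];
    double rn = rhsn;
    int it = 0;
    for (; it < maxit; ++it) {
      rn = std::sqrt(dot_faces(r, r));
      if (rn / rhsn <= rtol) break;
      applyA(pd, Ap);
      double alpha = rho / dot_faces(pd, Ap);
      for (int a = 0; a < 3; ++a)
        for (int f : actlist[a]) { z[a][f] += alpha * pd[a][f]; r[a][f] -= alpha * Ap[a][f]; }
      precond(r, w);
      double rho2 = dot_faces(r, w);
      double beta = rho2 / rho;
      rho = rho2;
      for (int a = 0; a < 3; ++a)
        for (int f : actlist[a]) pd[a][f] = w[a][f] + beta * pd[a][f];
    }
    iters = it;
    return rn / rhsn;
  }
};

// Stacked-vector views for the full saddle-point system: x = (u, v, w, p),
// length 4N; inactive faces and solid cells stay exactly zero throughout.
struct MinresOps {
  const StokesOp& op;
  long N;
  std::vector<double> diag_full[3]; // per-face diagonal (1 at inactive slots)

  explicit MinresOps(const StokesOp& o) : op(o), N(o.N) {
    for (int a = 0; a < 3; ++a) {
      diag_full[a].assign(N, 1.0);
      for (size_t q = 0; q < op.actlist[a].size(); ++q)
        diag_full[a][op.actlist[a][q]] = op.diag[a][q];
    }
  }

  // y = K x with K = [[A, G], [G^T, 0]], G^T u = -div u
  void applyK(const std::vector<double>& x, std::vector<double>& y) const {
    std::fill(y.begin(), y.end(), 0.0);
    const double* u[3] = {x.data(), x.data() + N, x.data() + 2 * N};
    const double* p = x.data() + 3 * N;
    double* yu[3] = {y.data(), y.data() + N, y.data() + 2 * N};
    double* yp = y.data() + 3 * N;
    for (int a = 0; a < 3; ++a) {
      const auto& lst = op.actlist[a];
      double cb[6];
      for (int b = 0; b < 3; ++b) cb[2 * b] = cb[2 * b + 1] = 1.0 / (op.h[b] * op.h[b]);
      double invh = 1.0 / op.h[a];
      for (size_t q = 0; q < lst.size(); ++q) {
        long f = lst[q];
        double v = op.diag[a][q] * u[a][f];
        for (int s = 0; s < 6; ++s) {
          int code = op.nb[a][s][q];
          if (code >= 0) v -= cb[s] * u[a][code];
        }
        // + grad p
        int k = (int)(f / ((long)op.nx * op.ny));
        int rem = (int)(f - (long)k * op.nx * op.ny);
        int j = rem / op.nx, i = rem % op.nx;
        int L[3] = {i, j, k};
        L[a] -= 1;
        if (L[a] < 0) L[a] += op.dim(a);
        v += (p[op.idx(i, j, k)] - p[op.idx(L[0], L[1], L[2])]) * invh;
        yu[a][f] = v;
      }
    }
    // pressure row: G^T u = -div u at fluid cells
    for (int cix : op.fluidcells) {
      long f = cix;
      int k = (int)(f / ((long)op.nx * op.ny));
      int rem = (int)(f - (long)k * op.nx * op.ny);
      int j = rem / op.nx, i = rem % op.nx;
      int c[3] = {i, j, k};
      double s = 0.0;
      for (int a = 0; a < 3; ++a) {
        double lo = u[a][f];
        int up[3] = {c[0], c[1], c[2]};
        up[a] += 1;
        double hi;
        int n = op.dim(a);
        if (up[a] >= n)
          hi = op.bc[a] == 0 ? u[a][op.idx(up[0] - (a == 0 ? n : 0),
                                           up[1] - (a == 1 ? n : 0),
                                           up[2] - (a == 2 ? n : 0))] : 0.0;
        else hi = u[a][op.idx(up[0], up[1], up[2])];
        s += (hi - lo) / op.h[a];
      }
      yp[f] = -s;
    }
  }

  // y = M^{-1} x: Jacobi on the velocity block, identity on pressure
  void applyMinv(const std::vector<double>& x, std::vector<double>& y) const {
    for (int a = 0; a < 3; ++a) {
      const double* xa = x.data() + (long)a * N;
      double* ya = y.data() + (long)a * N;
      const double* d = diag_full[a].data();
      for (long q = 0; q < N; ++q) ya[q] = xa[q] / d[q];
    }
    std::copy(x.begin() + 3 * N, x.end(), y.begin() + 3 * N);
  }
};

} // namespace

// Preconditioned MINRES (Paige-Saunders) on the Stokes saddle-point system.
// Runs until both the relative momentum residual and the continuity residual
// fall below `tol`; the recurrence residual target is tightened as needed.
// [[Rcpp::export]]
List stokes_solve_minres_cpp(IntegerVector solid, IntegerVector dims,
                             NumericVector h, int axis, IntegerVector bc,
                             NumericVector sx, NumericVector sy, NumericVector sz,
                             double tol = 1e-5, int max_iterations = 200000,
                             int check_every = 50) {
  StokesOp op;
  op.nx = dims[0]; op.ny = dims[1]; op.nz = dims[2];
  op.N = (long)op.nx * op.ny * op.nz;
  for (int a = 0; a < 3; ++a) { op.h[a] = h[a]; op.bc[a] = bc[a]; }
  op.solid = INTEGER(solid);
  op.build();
  if (op.actlist[axis].empty())
    stop("no-flow: no active faces along the flow axis");
  MinresOps M(op);
  const long N = op.N, NT = 4 * N;

  std::vector<double> b(NT, 0.0);
  for (int fidx : op.actlist[axis]) b[(long)axis * N + fidx] = 1.0;
  const NumericVector* src[3] = {&sx, &sy, &sz};
  for (int a = 0; a < 3; ++a)
    if (src[a]->size() == N)
      for (int fidx : op.actlist[a]) b[(long)a * N + fidx] += (*src[a])[fidx];
  double fnorm2 = 0.0;
  for (long q = 0; q < 3 * N; ++q) fnorm2 += b[q] * b[q];
  double fnorm = std::sqrt(fnorm2);

  std::vector<double> x(NT, 0.0), r1(b), r2(b), y(NT), v(NT), w(NT, 0.0),
      w1(NT, 0.0), w2(NT, 0.0), tmp(NT);
  M.applyMinv(r1, y);
  double beta1 = 0.0;
  for (long q = 0; q < NT; ++q) beta1 += r1[q] * y[q];
  beta1 = std::sqrt(beta1);
  double oldb = 0.0, beta = beta1, dbar = 0.0, epsln = 0.0,
         phibar = beta1, cs = -1.0, sn = 0.0, oldeps = 0.0;
  double res_mom = 1.0, res_cont = 1.0;
  int it = 0;
  auto true_residuals = [&]() {
    M.applyK(x, tmp);
    double mnum = 0.0, cnum = 0.0, unorm2 = 0.0;
    for (long q = 0; q < 3 * N; ++q) {
      double d = b[q] - tmp[q];
      mnum += d * d;
      unorm2 += x[q] * x[q];
    }
    for (long q = 3 * N; q < NT; ++q) cnum += tmp[q] * tmp[q];
    res_mom = std::sqrt(mnum) / fnorm;
    // continuity: RMS cell flux imbalance relative to the mean velocity
    // magnitude over the mean spacing (so it is dimensionless and comparable
    // to the momentum residual)
    double hmean = (op.h[0] + op.h[1] + op.h[2]) / 3.0;
    double uscale = std::sqrt(unorm2 / std::max<size_t>(1,
        op.actlist[0].size() + op.actlist[1].size() + op.actlist[2].size()));
    double dscale = uscale / hmean;
    size_t nf = std::max<size_t>(1, op.fluidcells.size());
    res_cont = dscale > 0 ? std::sqrt(cnum / nf) / dscale : 0.0;
  };
  double target = tol;
  for (it = 1; it <= max_iterations; ++it) {
    // v = y / beta
    for (long q = 0; q < NT; ++q) v[q] = y[q] / beta;
    M.applyK(v, tmp);
    if (it >= 2)
      for (long q = 0; q < NT; ++q) tmp[q] -= (beta / oldb) * r1[q];
    double alfa = 0.0;
    for (long q = 0; q < NT; ++q) alfa += v[q] * tmp[q];
    for (long q = 0; q < NT; ++q) tmp[q] -= (alfa / beta) * r2[q];
    r1.swap(r2);
    r2.swap(tmp);
    M.applyMinv(r2, y);
    oldb = beta;
    double beta2 = 0.0;
    for (long q = 0; q < NT; ++q) beta2 += r2[q] * y[q];
    if (beta2 < 0) stop("preconditioner lost positive definiteness");
    beta = std::sqrt(beta2);
    oldeps = epsln;
    double delta = cs * dbar + sn * alfa;
    double gbar = sn * dbar - cs * alfa;
    epsln = sn * beta;
    dbar = -cs * beta;
    double gamma = std::sqrt(gbar * gbar + beta * beta);
    if (gamma < 1e-300) gamma = 1e-300;
    cs = gbar / gamma;
    sn = beta / gamma;
    double phi = cs * phibar;
    phibar = sn * phibar;
    w1.swap(w2);
    w2.swap(w);
    for (long q = 0; q < NT; ++q)
      w[q] = (v[q] - oldeps * w1[q] - delta * w2[q]) / gamma;
    for (long q = 0; q < NT; ++q) x[q] += phi * w[q];
    if (phibar / beta1 <= target || it % check_every == 0 || it == max_iterations) {
      if (phibar / beta1 <= target) {
        true_residuals();
        if (res_mom <= tol && res_cont <= tol) break;
        target *= 0.1;  // recurrence residual not tight enough yet
      }
    }
  }
  true_residuals();

  NumericVector U(N), V(N), W(N), P(N);
  for (long q = 0; q < N; ++q) {
    U[q] = x[q]; V[q] = x[N + q]; W[q] = x[2 * N + q]; P[q] = x[3 * N + q];
  }
  // report max |div u|
  std::vector<double> dv(N, 0.0);
  std::vector<std::vector<double>> uf(3);
  for (int a = 0; a < 3; ++a)
    uf[a].assign(x.begin() + (long)a * N, x.begin() + (long)(a + 1) * N);
  op.divU(uf, dv);
  double maxdiv = 0.0;
  for (int cix : op.fluidcells) maxdiv = std::max(maxdiv, std::fabs(dv[cix]));
  return List::create(_["u"] = U, _["v"] = V, _["w"] = W, _["p"] = P,
                      _["outer_iterations"] = it,
                      _["inner_iterations"] = it,
                      _["res_continuity"] = res_cont,
                      _["res_momentum"] = res_mom,
                      _["max_div"] = maxdiv,
                      _["converged"] = (res_mom <= tol && res_cont <= tol));
}

// [[Rcpp::export]]
List stokes_solve_cpp(IntegerVector solid, IntegerVector dims, NumericVector h,
                      int axis, IntegerVector bc,
                      NumericVector sx, NumericVector sy, NumericVector sz,
                      double tol = 1e-5, int max_outer = 400,
                      double inner_tol = 1e-8, int max_inner = 20000) {
  StokesOp op;
  op.nx = dims[0]; op.ny = dims[1]; op.nz = dims[2];
  op.N = (long)op.nx * op.ny * op.nz;
  for (int a = 0; a < 3; ++a) { op.h[a] = h[a]; op.bc[a] = bc[a]; }
  op.solid = INTEGER(solid);
  op.build();

  if (op.actlist[axis].empty())
    stop("no-flow: no active faces along the flow axis");

  // body force + optional extra sources, masked to active faces
  std::vector<std::vector<double>> f(3), u(3), y(3), z(3);
  for (int a = 0; a < 3; ++a) {
    f[a].assign(op.N, 0.0); u[a].assign(op.N, 0.0);
    y[a].assign(op.N, 0.0); z[a].assign(op.N, 0.0);
  }
  for (int fidx : op.actlist[axis]) f[axis][fidx] = 1.0;
  const NumericVector* src[3] = {&sx, &sy, &sz};
  for (int a = 0; a < 3; ++a)
    if (src[a]->size() == op.N)
      for (int fidx : op.actlist[a]) f[a][fidx] += (*src[a])[fidx];

  int it_in = 0, inner_total = 0;
  op.solveA(f, u, inner_tol, max_inner, it_in);
  inner_total += it_in;

  std::vector<double> b(op.N, 0.0), p(op.N, 0.0), r(op.N), d(op.N), Sd(op.N);
  op.divU(u, b);
  for (long q = 0; q < op.N; ++q) b[q] = -b[q];
  op.sub_mean_cells(b);
  double bn = std::sqrt(op.dot_cells(b, b));

  r = b;
  d = r;
  double rho = op.dot_cells(r, r);
  int outer = 0;
  double relres = 1.0;
  if (bn > 0.0) {
    for (; outer < max_outer; ++outer) {
      relres = std::sqrt(rho) / bn;
      if (relres <= tol) break;
      op.gradP(d, y);
      op.solveA(y, z, inner_tol, max_inner, it_in);
      inner_total += it_in;
      op.divU(z, Sd);
      for (long q = 0; q < op.N; ++q) Sd[q] = -Sd[q];
      op.sub_mean_cells(Sd);
      double dSd = op.dot_cells(d, Sd);
      if (dSd <= 0) break; // loss of positive definiteness from inexact inner solves
      double alpha = rho / dSd;
      for (int cix : op.fluidcells) p[cix] += alpha * d[cix];
      for (int a = 0; a < 3; ++a)
        for (int fidx : op.actlist[a]) u[a][fidx] -= alpha * z[a][fidx];
      // Polak-Ribiere (tolerates inexact matvecs better than Fletcher-Reeves)
      double rr_old = rho, rdot = 0.0;
      for (int cix : op.fluidcells) {
        double rn2 = r[cix] - alpha * Sd[cix];
        rdot += rn2 * (rn2 - r[cix]);
        r[cix] = rn2;
      }
      op.sub_mean_cells(r);
      rho = op.dot_cells(r, r);
      double beta = std::max(0.0, rdot / rr_old);
      for (int cix : op.fluidcells) d[cix] = r[cix] + beta * d[cix];
    }
    relres = std::sqrt(rho) / bn;
  } else relres = 0.0;

  // momentum residual ||f - A u - G p|| / ||f||
  op.gradP(p, y);
  std::vector<std::vector<double>> Au(3);
  for (int a = 0; a < 3; ++a) Au[a].assign(op.N, 0.0);
  op.applyA(u, Au);
  double num = 0.0, den = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int fidx : op.actlist[a]) {
      double rm = f[a][fidx] - Au[a][fidx] - y[a][fidx];
      num += rm * rm;
      den += f[a][fidx] * f[a][fidx];
    }
  double res_mom = den > 0 ? std::sqrt(num / den) : 0.0;

  // max |div u| for reporting
  op.divU(u, Sd);
  double maxdiv = 0.0;
  for (int cix : op.fluidcells) maxdiv = std::max(maxdiv, std::fabs(Sd[cix]));

  NumericVector U(op.N), V(op.N), W(op.N), P(op.N);
  for (long q = 0; q < op.N; ++q) { U[q] = u[0][q]; V[q] = u[1][q]; W[q] = u[2][q]; P[q] = p[q]; }
  return List::create(_["u"] = U, _["v"] = V, _["w"] = W, _["p"] = P,
                      _["outer_iterations"] = outer,
                      _["inner_iterations"] = inner_total,
                      _["res_continuity"] = relres,
                      _["res_momentum"] = res_mom,
                      _["max_div"] = maxdiv,
                      _["converged"] = relres <= tol);
}

// [[Rcpp::export]]
bool percolates_cpp(IntegerVector solid, IntegerVector dims, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long N = (long)nx * ny * nz;
  const int* sol = INTEGER(solid);
  auto idx = [&](int i, int j, int k) { return i + (long)nx * (j + (long)ny * k); };
  int n[3] = {nx, ny, nz};
  std::vector<uint8_t> seen(N, 0);
  std::vector<int> stack;
  // seed the lower slice along `axis`
  int lo[3] = {0, 0, 0}, hi[3] = {nx, ny, nz};
  hi[axis] = 1;
  for (int k = lo[2]; k < hi[2]; ++k)
    for (int j = lo[1]; j < hi[1]; ++j)
      for (int i = lo[0]; i < hi[0]; ++i) {
        long q = idx(i, j, k);
        if (!sol[q]) { seen[q] = 1; stack.push_back((int)q); }
      }
  while (!stack.empty()) {
    long q = stack.back(); stack.pop_back();
    int k = (int)(q / ((long)nx * ny));
    int rem = (int)(q - (long)k * nx * ny);
    int j = rem / nx, i = rem % nx;
    int c0[3] = {i, j, k};
    for (int b = 0; b < 3; ++b)
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        int c[3] = {c0[0], c0[1], c0[2]};
        c[b] += sgn;
        if (b == axis) {
          if (c[b] < 0 || c[b] >= n[b]) continue;  // no wrap along the tested axis
        } else {
          if (c[b] < 0) c[b] += n[b];
          else if (c[b] >= n[b]) c[b] -= n[b];
        }
        long q2 = idx(c[0], c[1], c[2]);
        if (!seen[q2] && !sol[q2]) { seen[q2] = 1; stack.push_back((int)q2); }
      }
  }
  // crossed iff a reached cell on the top slice is wrap-adjacent to a fluid
  // cell on the seeded bottom slice
  int top[3] = {0, 0, 0};
  for (int k = (axis == 2 ? nz - 1 : 0); k < (axis == 2 ? nz : nz); ++k)
    for (int j = (axis == 1 ? ny - 1 : 0); j < (axis == 1 ? ny : ny); ++j)
      for (int i = (axis == 0 ? nx - 1 : 0); i < (axis == 0 ? nx : nx); ++i) {
        (void)top;
        long q = idx(i, j, k);
        if (!seen[q]) continue;
        int c[3] = {i, j, k};
        c[axis] = 0;
        if (!sol[idx(c[0], c[1], c[2])]) return true;
      }
  return false;
}
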