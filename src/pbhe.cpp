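#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Perfusionless Pennes bioheat stepping on a regular grid:
//   VHC dT/dt = div(kappa grad T) + Q * 1(t < heat_duration)
// 7-point stencil with harmonic-mean face conductivities. Temperature is the
// rise above baseline; Dirichlet (rise = 0, boundary voxels held fixed) or
// Neumann (insulated) outer boundaries. Schemes: explicit FTCS and
// Douglas-Gunn ADI (unconditionally stable).
//
// Face weights are precomputed once: wm_d[v], wp_d[v] are the neighbor
// coupling coefficients (1/s) of voxel v along dimension d, zero across
// domain faces (Neumann) and zero everywhere on fixed boundary voxels
// (Dirichlet), which turns their implicit rows into identities.
//
// Frame averaging is done in-stream: `frame_steps` gives the number of time
// steps in each output frame; the frame value is the mean of the post-step
// fields inside the window.

static inline double harm(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

struct Workspace {
  int nx, ny, nz;
  size_t n;
  // per-dimension neighbor weights
  std::vector<double> wm[3], wp[3];
  size_t stride[3];
  int len[3];
};

static void build_weights(Workspace &w, const double *kap, const double *vhc,
                          double inv_dx2, int boundary) {
  const int nx = w.nx, ny = w.ny, nz = w.nz;
  w.stride[0] = 1; w.stride[1] = (size_t)nx; w.stride[2] = (size_t)nx * ny;
  w.len[0] = nx; w.len[1] = ny; w.len[2] = nz;
  for (int d = 0; d < 3; ++d) {
    w.wm[d].assign(w.n, 0.0);
    w.wp[d].assign(w.n, 0.0);
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t v = (size_t)i + (size_t)nx * j + (size_t)nx * ny * k;
        const bool fixed =
            boundary == 0 && (i == 0 || i == nx - 1 || j == 0 ||
                              j == ny - 1 || k == 0 || k == nz - 1);
        if (fixed) continue;
        const int idx[3] = {i, j, k};
        for (int d = 0; d < 3; ++d) {
          const size_t s = w.stride[d];
          if (idx[d] > 0)
            w.wm[d][v] = harm(kap[v], kap[v - s]) * inv_dx2 / vhc[v];
          if (idx[d] < w.len[d] - 1)
            w.wp[d][v] = harm(kap[v], kap[v + s]) * inv_dx2 / vhc[v];
        }
      }
}

// out = A_d T using precomputed weights (0 on fixed voxels by construction)
static void apply_op(const Workspace &w, int d, const double *T,
                     double *out) {
  const size_t s = w.stride[d], n = w.n;
  const double *wm = w.wm[d].data(), *wp = w.wp[d].data();
  // interior strides never reach outside because boundary weights are zero,
  // but guard the array ends explicitly
  for (size_t v = 0; v < n; ++v) {
    double acc = 0.0;
    if (wp[v] != 0.0) acc += wp[v] * (T[v + s] - T[v]);
    if (wm[v] != 0.0) acc -= wm[v] * (T[v] - T[v - s]);
    out[v] = acc;
  }
}

// Solve (I - coef * A_d) X = RHS line-by-line (Thomas algorithm).
static void solve_dim(const Workspace &w, int d, double coef,
                      const double *rhs, double *X) {
  const size_t s = w.stride[d];
  const int nd = w.len[d];
  const double *wm = w.wm[d].data(), *wp = w.wp[d].data();
  const int du = (d == 0) ? 1 : 0;             // u runs over x unless d == 0
  const int nu = (d == 0) ? w.ny : w.nx;
  const int nv = (d == 2) ? w.ny : w.nz;
  const size_t su = (d == 0) ? w.stride[1] : w.stride[0];
  const size_t sv = (d == 2) ? w.stride[1] : w.stride[2];
  (void)du;
  std::vector<double> cp(nd), dp(nd);
  for (int v2 = 0; v2 < nv; ++v2)
    for (int u = 0; u < nu; ++u) {
      const size_t base = (size_t)u * su + (size_t)v2 * sv;
      // Thomas forward sweep; diagonal = 1 + coef*(wm+wp)
      {
        const size_t w0 = base;
        const double b0 = 1.0 + coef * (wm[w0] + wp[w0]);
        cp[0] = -coef * wp[w0] / b0;
        dp[0] = rhs[w0] / b0;
      }
      for (int t = 1; t < nd; ++t) {
        const size_t wt = base + (size_t)t * s;
        const double a = -coef * wm[wt];
        const double b = 1.0 + coef * (wm[wt] + wp[wt]);
        const double m = b - a * cp[t - 1];
        cp[t] = -coef * wp[wt] / m;
        dp[t] = (rhs[wt] - a * dp[t - 1]) / m;
      }
      X[base + (size_t)(nd - 1) * s] = dp[nd - 1];
      for (int t = nd - 2; t >= 0; --t)
        X[base + (size_t)t * s] =
            dp[t] - cp[t] * X[base + (size_t)(t + 1) * s];
    }
}

// [[Rcpp::export]]
List pbhe_run_cpp(NumericVector T0, NumericVector Q, NumericVector kappa,
                  NumericVector vhc, IntegerVector dims, double dx, double dt,
                  IntegerVector frame_steps, int heat_steps, int scheme,
                  int boundary, int trace_index, int dense_k0, int dense_k1) {
  Workspace w;
  w.nx = dims[0]; w.ny = dims[1]; w.nz = dims[2];
  w.n = (size_t)w.nx * w.ny * w.nz;
  const size_t n = w.n;
  build_weights(w, kappa.begin(), vhc.begin(), 1.0 / (dx * dx), boundary);

  int n_steps = 0;
  for (int f = 0; f < frame_steps.size(); ++f) n_steps += frame_steps[f];
  const int nf = frame_steps.size();

  std::vector<double> T(T0.begin(), T0.end());
  std::vector<double> S(n);
  for (size_t v = 0; v < n; ++v) S[v] = Q[v] / vhc[v];
  if (boundary == 0) { // no source on pinned boundary voxels
    for (int k = 0; k < w.nz; ++k)
      for (int j = 0; j < w.ny; ++j)
        for (int i = 0; i < w.nx; ++i)
          if (i == 0 || i == w.nx - 1 || j == 0 || j == w.ny - 1 || k == 0 ||
              k == w.nz - 1)
            S[(size_t)i + (size_t)w.nx * j + (size_t)w.nx * w.ny * k] = 0.0;
  }

  std::vector<double> ax(n), ay(n), az(n), rhs(n), work(n);
  NumericVector frames((R_xlen_t)n * nf);
  NumericVector trace(trace_index >= 0 ? n_steps : 0);
  const int nk_dense = (dense_k0 >= 0) ? (dense_k1 - dense_k0 + 1) : 0;
  NumericVector dense(nk_dense > 0
                          ? (R_xlen_t)w.nx * w.ny * nk_dense * n_steps
                          : 0);
  std::vector<double> facc(n, 0.0);
  int f_idx = 0, f_count = 0;

  for (int step = 0; step < n_steps; ++step) {
    const bool heating = step < heat_steps;
    if (scheme == 0) { // explicit FTCS
      apply_op(w, 0, T.data(), ax.data());
      apply_op(w, 1, T.data(), ay.data());
      apply_op(w, 2, T.data(), az.data());
      for (size_t v = 0; v < n; ++v) {
        double upd = T[v] + dt * (ax[v] + ay[v] + az[v]);
        if (heating) upd += dt * S[v];
        work[v] = upd;
      }
      T.swap(work);
    } else { // Douglas-Gunn ADI
      apply_op(w, 0, T.data(), ax.data());
      apply_op(w, 1, T.data(), ay.data());
      apply_op(w, 2, T.data(), az.data());
      if (heating) {
        for (size_t v = 0; v < n; ++v)
          rhs[v] = T[v] + dt * (0.5 * ax[v] + ay[v] + az[v]) + dt * S[v];
      } else {
        for (size_t v = 0; v < n; ++v)
          rhs[v] = T[v] + dt * (0.5 * ax[v] + ay[v] + az[v]);
      }
      solve_dim(w, 0, 0.5 * dt, rhs.data(), work.data()); // T*
      for (size_t v = 0; v < n; ++v) rhs[v] = work[v] - 0.5 * dt * ay[v];
      solve_dim(w, 1, 0.5 * dt, rhs.data(), work.data()); // T**
      for (size_t v = 0; v < n; ++v) rhs[v] = work[v] - 0.5 * dt * az[v];
      solve_dim(w, 2, 0.5 * dt, rhs.data(), T.data());    // T^{n+1}
    }

    if (trace_index >= 0) trace[step] = T[(size_t)trace_index];
    if (nk_dense > 0) {
      const size_t plane = (size_t)w.nx * w.ny;
      double *dst = REAL(dense) + (R_xlen_t)plane * nk_dense * step;
      for (int k = 0; k < nk_dense; ++k)
        std::copy(T.data() + plane * (dense_k0 + k),
                  T.data() + plane * (dense_k0 + k + 1), dst + plane * k);
    }
    for (size_t v = 0; v < n; ++v) facc[v] += T[v];
    if (++f_count == frame_steps[f_idx]) {
      double *dst = REAL(frames) + (R_xlen_t)n * f_idx;
      const double inv = 1.0 / f_count;
      for (size_t v = 0; v < n; ++v) { dst[v] = facc[v] * inv; facc[v] = 0.0; }
      f_idx++; f_count = 0;
    }
  }

  frames.attr("dim") = IntegerVector::create(w.nx, w.ny, w.nz, nf);
  NumericVector Tfinal(T.begin(), T.end());
  Tfinal.attr("dim") = IntegerVector::create(w.nx, w.ny, w.nz);
  List out = List::create(_["frames"] = frames, _["final"] = Tfinal,
                          _["trace"] = trace);
  if (nk_dense > 0) {
    dense.attr("dim") =
        IntegerVector::create(w.nx, w.ny, nk_dense, n_steps);
    out["dense"] = dense;
  }
  return out;
}
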