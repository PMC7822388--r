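// Parallel-beam projection kernels and SART sweeps.
//
// Conventions (fixed package-wide, asserted by tests):
//   * image is N x N; matrix element (i, j) (0-based here) sits at
//     x = (i - (N-1)/2) * psz, y = (j - (N-1)/2) * psz, rotation center at
//     the image center;
//   * detector cell u (0-based) has signed offset t = (u - (U-1)/2) * pitch,
//     cell 0 at the negative edge;
//   * a view at angle phi (from the +x axis) measures line integrals along
//     rays x*cos(phi) + y*sin(phi) = t;
//   * sinograms are n_views x n_det, one row per view.
//
// Forward projection is Joseph-style (ray-driven, linear interpolation along
// the minor axis, step length psz / max(|cos|,|sin|)); cpp_back_joseph is its
// exact transpose. cpp_back_pixel is the pixel-driven backprojector (linear
// detector interpolation); cpp_forward_pixel is its exact transpose, kept as
// the matched pair for adjointness checks.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Geom {
  int N;        // image side
  int U;        // detector cells
  double psz;   // pixel size (cm)
  double pitch; // detector pitch (cm)
};

// Interpolation-index parameters of one ray: along the stepped (major) axis
// with index k, the continuous minor-axis index is m0 + k * dm.  The two
// divisions are hoisted out of the per-sample loop.
struct RayIdx {
  bool xmajor;  // |cos| >= |sin|: step over y rows, interpolate along x
  double m0, dm, w;
};

inline RayIdx ray_idx(const Geom& gm, double c, double sn, double t) {
  RayIdx r;
  const double half = (gm.N - 1) / 2.0;
  r.xmajor = std::fabs(c) >= std::fabs(sn);
  if (r.xmajor) {
    r.dm = -sn / c;
    r.m0 = t / (c * gm.psz) - half * r.dm + half;
    r.w = gm.psz / std::fabs(c);
  } else {
    r.dm = -c / sn;
    r.m0 = t / (sn * gm.psz) - half * r.dm + half;
    r.w = gm.psz / std::fabs(sn);
  }
  return r;
}

// Joseph line integral for one ray; returns sum of interpolated pixel values
// times the step length.
inline double joseph_ray(const double* img, const Geom& gm, double c,
                         double sn, double t) {
  const int N = gm.N;
  const RayIdx r = ray_idx(gm, c, sn, t);
  double acc = 0.0;
  if (r.xmajor) {
    for (int j = 0; j < N; ++j) {
      const double xi = r.m0 + j * r.dm;
      const int i0 = (int)std::floor(xi);
      const double fr = xi - i0;
      if (i0 >= 0 && i0 < N) acc += (1.0 - fr) * img[i0 + j * N];
      if (i0 + 1 >= 0 && i0 + 1 < N) acc += fr * img[i0 + 1 + j * N];
    }
  } else {
    for (int i = 0; i < N; ++i) {
      const double yi = r.m0 + i * r.dm;
      const int j0 = (int)std::floor(yi);
      const double fr = yi - j0;
      if (j0 >= 0 && j0 < N) acc += (1.0 - fr) * img[i + j0 * N];
      if (j0 + 1 >= 0 && j0 + 1 < N) acc += fr * img[i + (j0 + 1) * N];
    }
  }
  return acc * r.w;
}

// Fused two-image variant (one index computation, two accumulations).
inline void joseph_ray2(const double* a, const double* b, const Geom& gm,
                        double c, double sn, double t, double* va,
                        double* vb) {
  const int N = gm.N;
  const RayIdx r = ray_idx(gm, c, sn, t);
  double aa = 0.0, ab = 0.0;
  if (r.xmajor) {
    for (int j = 0; j < N; ++j) {
      const double xi = r.m0 + j * r.dm;
      const int i0 = (int)std::floor(xi);
      const double fr = xi - i0;
      if (i0 >= 0 && i0 < N) {
        const int k = i0 + j * N;
        aa += (1.0 - fr) * a[k]; ab += (1.0 - fr) * b[k];
      }
      if (i0 + 1 >= 0 && i0 + 1 < N) {
        const int k = i0 + 1 + j * N;
        aa += fr * a[k]; ab += fr * b[k];
      }
    }
  } else {
    for (int i = 0; i < N; ++i) {
      const double yi = r.m0 + i * r.dm;
      const int j0 = (int)std::floor(yi);
      const double fr = yi - j0;
      if (j0 >= 0 && j0 < N) {
        const int k = i + j0 * N;
        aa += (1.0 - fr) * a[k]; ab += (1.0 - fr) * b[k];
      }
      if (j0 + 1 >= 0 && j0 + 1 < N) {
        const int k = i + (j0 + 1) * N;
        aa += fr * a[k]; ab += fr * b[k];
      }
    }
  }
  *va = aa * r.w; *vb = ab * r.w;
}

// Transpose of joseph_ray: scatter val along the ray.
inline void joseph_ray_t(double* img, const Geom& gm, double c, double sn,
                         double t, double val) {
  const int N = gm.N;
  const RayIdx r = ray_idx(gm, c, sn, t);
  const double v = val * r.w;
  if (r.xmajor) {
    for (int j = 0; j < N; ++j) {
      const double xi = r.m0 + j * r.dm;
      const int i0 = (int)std::floor(xi);
      const double fr = xi - i0;
      if (i0 >= 0 && i0 < N) img[i0 + j * N] += (1.0 - fr) * v;
      if (i0 + 1 >= 0 && i0 + 1 < N) img[i0 + 1 + j * N] += fr * v;
    }
  } else {
    for (int i = 0; i < N; ++i) {
      const double yi = r.m0 + i * r.dm;
      const int j0 = (int)std::floor(yi);
      const double fr = yi - j0;
      if (j0 >= 0 && j0 < N) img[i + j0 * N] += (1.0 - fr) * v;
      if (j0 + 1 >= 0 && j0 + 1 < N) img[i + (j0 + 1) * N] += fr * v;
    }
  }
}

inline double det_t(const Geom& gm, int u) {
  return (u - (gm.U - 1) / 2.0) * gm.pitch;
}

// -d/du with central differences, one-sided at the boundary cells.
inline void drow(const double* q, double* out, int U, double pitch) {
  out[0] = -(q[1] - q[0]) / pitch;
  for (int u = 1; u < U - 1; ++u)
    out[u] = -(q[u + 1] - q[u - 1]) / (2.0 * pitch);
  out[U - 1] = -(q[U - 1] - q[U - 2]) / pitch;
}

// Transpose of drow.
inline void drow_t(const double* r, double* out, int U, double pitch) {
  for (int u = 0; u < U; ++u) out[u] = 0.0;
  out[0] += r[0] / pitch;
  out[1] += -r[0] / pitch;
  for (int u = 1; u < U - 1; ++u) {
    out[u - 1] += r[u] / (2.0 * pitch);
    out[u + 1] += -r[u] / (2.0 * pitch);
  }
  out[U - 2] += r[U - 1] / pitch;
  out[U - 1] += -r[U - 1] / pitch;
}

// Gradient descent on ||D e - r||^2 from a zero start, fixed step 1/L with
// the Gershgorin bound L = 4 / pitch^2.
inline void dinv_gd_row(const double* r, double* e, int U, double pitch,
                        int n_steps) {
  std::vector<double> de(U), grad(U);
  const double step = pitch * pitch / 4.0;
  for (int u = 0; u < U; ++u) e[u] = 0.0;
  for (int s = 0; s < n_steps; ++s) {
    drow(e, de.data(), U, pitch);
    for (int u = 0; u < U; ++u) de[u] -= r[u];
    drow_t(de.data(), grad.data(), U, pitch);
    for (int u = 0; u < U; ++u) e[u] -= step * grad[u];
  }
}

// Anchored gradient descent continuing from the caller-supplied start:
// minimizes ||D e - r||^2 over e with e[0] pinned to 0 (the zero boundary
// condition at the detector edge).
inline void dinv_gd_anchored_row(const double* r, double* e, int U,
                                 double pitch, int n_steps) {
  std::vector<double> de(U), grad(U);
  const double step = pitch * pitch / 4.0;
  e[0] = 0.0;
  for (int s = 0; s < n_steps; ++s) {
    drow(e, de.data(), U, pitch);
    for (int u = 0; u < U; ++u) de[u] -= r[u];
    drow_t(de.data(), grad.data(), U, pitch);
    for (int u = 1; u < U; ++u) e[u] -= step * grad[u];
  }
}

// Running-sum antiderivative consistent with drow, left boundary pinned to 0:
// e[1] = -pitch * r[0]; e[u+1] = e[u-1] - 2*pitch*r[u].
inline void dinv_cum_row(const double* r, double* e, int U, double pitch) {
  e[0] = 0.0;
  if (U > 1) e[1] = -pitch * r[0];
  for (int u = 1; u < U - 1; ++u) e[u + 1] = e[u - 1] - 2.0 * pitch * r[u];
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forward_joseph(const NumericMatrix& img,
                                 const NumericVector& angles, int n_det,
                                 double pitch, double psz) {
  const int N = img.nrow(), V = angles.size();
  Geom gm{N, n_det, psz, pitch};
  NumericMatrix sino(V, n_det);
  for (int v = 0; v < V; ++v) {
    const double c = std::cos(angles[v]), sn = std::sin(angles[v]);
    for (int u = 0; u < n_det; ++u)
      sino(v, u) = joseph_ray(img.begin(), gm, c, sn, det_t(gm, u));
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_joseph(const NumericMatrix& sino, int n_img,
                              const NumericVector& angles, double pitch,
                              double psz) {
  const int V = sino.nrow(), U = sino.ncol();
  Geom gm{n_img, U, psz, pitch};
  NumericMatrix img(n_img, n_img);
  for (int v = 0; v < V; ++v) {
    const double c = std::cos(angles[v]), sn = std::sin(angles[v]);
    for (int u = 0; u < U; ++u)
      joseph_ray_t(img.begin(), gm, c, sn, det_t(gm, u), sino(v, u));
  }
  return img;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_pixel(const NumericMatrix& sino, int n_img,
                             const NumericVector& angles, double pitch,
                             double psz) {
  const int V = sino.nrow(), U = sino.ncol();
  NumericMatrix img(n_img, n_img);
  const double half = (n_img - 1) / 2.0;
  const double uhalf = (U - 1) / 2.0;
  for (int v = 0; v < V; ++v) {
    const double c = std::cos(angles[v]), sn = std::sin(angles[v]);
    const double dui = c * psz / pitch;
    for (int j = 0; j < n_img; ++j) {
      const double y = (j - half) * psz;
      const double ui0 = (y * sn - half * psz * c) / pitch + uhalf;
      for (int i = 0; i < n_img; ++i) {
        const double ui = ui0 + i * dui;
        const int u0 = (int)std::floor(ui);
        const double fr = ui - u0;
        double val = 0.0;
        if (u0 >= 0 && u0 < U) val += (1.0 - fr) * sino(v, u0);
        if (u0 + 1 >= 0 && u0 + 1 < U) val += fr * sino(v, u0 + 1);
        img(i, j) += val;
      }
    }
  }
  return img;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_pixel(const NumericMatrix& img,
                                const NumericVector& angles, int n_det,
                                double pitch, double psz) {
  const int N = img.nrow(), V = angles.size();
  NumericMatrix sino(V, n_det);
  const double half = (N - 1) / 2.0;
  const double uhalf = (n_det - 1) / 2.0;
  for (int v = 0; v < V; ++v) {
    const double c = std::cos(angles[v]), sn = std::sin(angles[v]);
    const double dui = c * psz / pitch;
    for (int j = 0; j < N; ++j) {
      const double y = (j - half) * psz;
      const double ui0 = (y * sn - half * psz * c) / pitch + uhalf;
      for (int i = 0; i < N; ++i) {
        const double ui = ui0 + i * dui;
        const int u0 = (int)std::floor(ui);
        const double fr = ui - u0;
        const double val = img(i, j);
        if (u0 >= 0 && u0 < n_det) sino(v, u0) += (1.0 - fr) * val;
        if (u0 + 1 >= 0 && u0 + 1 < n_det) sino(v, u0 + 1) += fr * val;
      }
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_diff_rows(const NumericMatrix& sino, double pitch) {
  const int V = sino.nrow(), U = sino.ncol();
  NumericMatrix out(V, U);
  std::vector<double> q(U), r(U);
  for (int v = 0; v < V; ++v) {
    for (int u = 0; u < U; ++u) q[u] = sino(v, u);
    drow(q.data(), r.data(), U, pitch);
    for (int u = 0; u < U; ++u) out(v, u) = r[u];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dinv_cumulative(const NumericMatrix& sino, double pitch) {
  const int V = sino.nrow(), U = sino.ncol();
  NumericMatrix out(V, U);
  std::vector<double> r(U), e(U);
  for (int v = 0; v < V; ++v) {
    for (int u = 0; u < U; ++u) r[u] = sino(v, u);
    dinv_cum_row(r.data(), e.data(), U, pitch);
    for (int u = 0; u < U; ++u) out(v, u) = e[u];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dinv_gd(const NumericMatrix& sino, double pitch,
                          int n_steps) {
  const int V = sino.nrow(), U = sino.ncol();
  NumericMatrix out(V, U);
  std::vector<double> r(U), e(U);
  for (int v = 0; v < V; ++v) {
    for (int u = 0; u < U; ++u) r[u] = sino(v, u);
    dinv_gd_row(r.data(), e.data(), U, pitch, n_steps);
    for (int u = 0; u < U; ++u) out(v, u) = e[u];
  }
  return out;
}

namespace {

// One SART view update: given per-cell normalized residual rows (already
// divided by the ray sums A_{u,+}), backproject along Joseph weights and
// divide by the per-view pixel weight A_{+,j}.  Two residual channels share
// the weight pass.
void sart_view_update(double* f, double* g, const Geom& gm, double c,
                      double sn, const double* rf, const double* rg,
                      double relax) {
  const int N = gm.N, U = gm.U;
  const bool two = (g != nullptr);
  std::vector<double> bpf(N * N, 0.0), wsum(N * N, 0.0);
  std::vector<double> bpg(two ? N * N : 0, 0.0);
  for (int u = 0; u < U; ++u) {
    const RayIdx r = ray_idx(gm, c, sn, det_t(gm, u));
    const double w = r.w;
    const double vf = (rf != nullptr) ? rf[u] * w : 0.0;
    const double vg = (two && rg != nullptr) ? rg[u] * w : 0.0;
    if (r.xmajor) {
      for (int j = 0; j < N; ++j) {
        const double xi = r.m0 + j * r.dm;
        const int i0 = (int)std::floor(xi);
        const double fr = xi - i0;
        if (i0 >= 0 && i0 < N) {
          const int k = i0 + j * N;
          bpf[k] += (1.0 - fr) * vf; wsum[k] += (1.0 - fr) * w;
          if (two) bpg[k] += (1.0 - fr) * vg;
        }
        if (i0 + 1 >= 0 && i0 + 1 < N) {
          const int k = i0 + 1 + j * N;
          bpf[k] += fr * vf; wsum[k] += fr * w;
          if (two) bpg[k] += fr * vg;
        }
      }
    } else {
      for (int i = 0; i < N; ++i) {
        const double yi = r.m0 + i * r.dm;
        const int j0 = (int)std::floor(yi);
        const double fr = yi - j0;
        if (j0 >= 0 && j0 < N) {
          const int k = i + j0 * N;
          bpf[k] += (1.0 - fr) * vf; wsum[k] += (1.0 - fr) * w;
          if (two) bpg[k] += (1.0 - fr) * vg;
        }
        if (j0 + 1 >= 0 && j0 + 1 < N) {
          const int k = i + (j0 + 1) * N;
          bpf[k] += fr * vf; wsum[k] += fr * w;
          if (two) bpg[k] += fr * vg;
        }
      }
    }
  }
  for (int k = 0; k < N * N; ++k) {
    if (wsum[k] > 1e-12) {
      f[k] += relax * bpf[k] / wsum[k];
      if (two) g[k] += relax * bpg[k] / wsum[k];
    }
  }
}

} // namespace

// One full sweep of the coupled two-channel SART update.  In per-sweep mode
// (per_view = false) all residuals are computed once from the entry iterate;
// in per-view mode each view's residual row is recomputed from the current
// iterate just before its update.  rowsum holds the ray sums A_{u,+}
// (forward projection of a unit image), precomputed by the caller.
// [[Rcpp::export]]
List cpp_pamd_sweep(const NumericMatrix& f0, const NumericMatrix& g0,
                    const NumericMatrix& M, const NumericMatrix& theta,
                    const NumericVector& angles, double pitch, double psz,
                    double mu1, double mu2, double d1, double d2,
                    double relax, int inner_steps,
                    const NumericMatrix& rowsum, const IntegerVector& order,
                    bool per_view, int inner_mode,
                    NumericMatrix eDth_state) {
  const int N = f0.nrow(), V = angles.size(), U = M.ncol();
  Geom gm{N, U, psz, pitch};
  NumericMatrix f = clone(f0), g = clone(g0);
  const double det = mu1 * d2 - mu2 * d1;

  std::vector<double> rf(U), rg(U), eM(U), eTh(U), eDth(U);
  std::vector<double> mf(U), mg(U);

  NumericMatrix eM_all, eDth_all;
  double res_m = 0.0, res_th = 0.0;
  if (!per_view) {
    // residuals for every view from the entry iterate
    eM_all = NumericMatrix(V, U);
    NumericMatrix thres(V, U);
    for (int v = 0; v < V; ++v) {
      const double c = std::cos(angles[v]), sn = std::sin(angles[v]);
      for (int u = 0; u < U; ++u)
        joseph_ray2(f.begin(), g.begin(), gm, c, sn, det_t(gm, u),
                    &mf[u], &mg[u]);
      std::vector<double> phi(U), dphi(U);
      for (int u = 0; u < U; ++u) {
        eM_all(v, u) = M(v, u) - (mu1 * mf[u] + mu2 * mg[u]);
        phi[u] = d1 * mf[u] + d2 * mg[u];
      }
      drow(phi.data(), dphi.data(), U, pitch);
      for (int u = 0; u < U; ++u) thres(v, u) = theta(v, u) - dphi[u];
    }
    if (inner_mode == 1) {
      eDth_all = cpp_dinv_cumulative(thres, pitch);
    } else if (inner_mode == 2) {
      eDth_all = NumericMatrix(V, U);
      std::vector<double> rr(U), ee(U);
      for (int v = 0; v < V; ++v) {
        for (int u = 0; u < U; ++u) { rr[u] = thres(v, u); ee[u] = eDth_state(v, u); }
        dinv_gd_anchored_row(rr.data(), ee.data(), U, pitch, inner_steps);
        for (int u = 0; u < U; ++u) { eDth_all(v, u) = ee[u]; eDth_state(v, u) = ee[u]; }
      }
    } else {
      eDth_all = cpp_dinv_gd(thres, pitch, inner_steps);
    }
    for (int v = 0; v < V; ++v)
      for (int u = 0; u < U; ++u) {
        res_m += eM_all(v, u) * eM_all(v, u);
        res_th += thres(v, u) * thres(v, u);
      }
  }

  for (int k = 0; k < order.size(); ++k) {
    const int v = order[k];
    const double c = std::cos(angles[v]), sn = std::sin(angles[v]);
    if (per_view) {
      std::vector<double> phi(U), dphi(U);
      for (int u = 0; u < U; ++u) {
        joseph_ray2(f.begin(), g.begin(), gm, c, sn, det_t(gm, u),
                    &mf[u], &mg[u]);
        eM[u] = M(v, u) - (mu1 * mf[u] + mu2 * mg[u]);
        phi[u] = d1 * mf[u] + d2 * mg[u];
      }
      drow(phi.data(), dphi.data(), U, pitch);
      for (int u = 0; u < U; ++u) dphi[u] = theta(v, u) - dphi[u];
      if (inner_mode == 1) {
        dinv_cum_row(dphi.data(), eDth.data(), U, pitch);
      } else if (inner_mode == 2) {
        for (int u = 0; u < U; ++u) eDth[u] = eDth_state(v, u);
        dinv_gd_anchored_row(dphi.data(), eDth.data(), U, pitch, inner_steps);
        for (int u = 0; u < U; ++u) eDth_state(v, u) = eDth[u];
      } else {
        dinv_gd_row(dphi.data(), eDth.data(), U, pitch, inner_steps);
      }
      for (int u = 0; u < U; ++u) {
        res_m += eM[u] * eM[u];
        res_th += dphi[u] * dphi[u];
      }
    } else {
      for (int u = 0; u < U; ++u) {
        eM[u] = eM_all(v, u);
        eDth[u] = eDth_all(v, u);
      }
    }
    for (int u = 0; u < U; ++u) {
      const double rs = rowsum(v, u);
      if (rs > 1e-12) {
        rf[u] = (d2 * eM[u] - mu2 * eDth[u]) / det / rs;
        rg[u] = (d1 * eM[u] - mu1 * eDth[u]) / (-det) / rs;
      } else {
        rf[u] = 0.0; rg[u] = 0.0;
      }
    }
    sart_view_update(f.begin(), g.begin(), gm, c, sn, rf.data(), rg.data(),
                     relax);
  }
  return List::create(_["f"] = f, _["g"] = g,
                      _["res_m"] = std::sqrt(res_m),
                      _["res_theta"] = std::sqrt(res_th));
}

// Single-channel SART sweep (absorption sinogram, or differential-phase with
// the residual routed through the Eq-(20)-style gradient-descent inversion).
// [[Rcpp::export]]
List cpp_sart_sweep(const NumericMatrix& x0, const NumericMatrix& b,
                    const NumericVector& angles, double pitch, double psz,
                    bool differential, double relax, int inner_steps,
                    const NumericMatrix& rowsum, const IntegerVector& order,
                    bool per_view, int inner_mode,
                    NumericMatrix e_state) {
  const int N = x0.nrow(), V = angles.size(), U = b.ncol();
  Geom gm{N, U, psz, pitch};
  NumericMatrix x = clone(x0);
  std::vector<double> ax(U), e(U), r(U);
  double res = 0.0;

  NumericMatrix e_all;
  if (!per_view) {
    NumericMatrix resid(V, U);
    for (int v = 0; v < V; ++v) {
      const double c = std::cos(angles[v]), sn = std::sin(angles[v]);
      for (int u = 0; u < U; ++u)
        ax[u] = joseph_ray(x.begin(), gm, c, sn, det_t(gm, u));
      if (differential) {
        std::vector<double> dax(U);
        drow(ax.data(), dax.data(), U, pitch);
        for (int u = 0; u < U; ++u) resid(v, u) = b(v, u) - dax[u];
      } else {
        for (int u = 0; u < U; ++u) resid(v, u) = b(v, u) - ax[u];
      }
    }
    for (int v = 0; v < V; ++v)
      for (int u = 0; u < U; ++u) res += resid(v, u) * resid(v, u);
    if (!differential) {
      e_all = resid;
    } else if (inner_mode == 1) {
      e_all = cpp_dinv_cumulative(resid, pitch);
    } else if (inner_mode == 2) {
      e_all = NumericMatrix(V, U);
      std::vector<double> rr(U), ee(U);
      for (int v = 0; v < V; ++v) {
        for (int u = 0; u < U; ++u) { rr[u] = resid(v, u); ee[u] = e_state(v, u); }
        dinv_gd_anchored_row(rr.data(), ee.data(), U, pitch, inner_steps);
        for (int u = 0; u < U; ++u) { e_all(v, u) = ee[u]; e_state(v, u) = ee[u]; }
      }
    } else {
      e_all = cpp_dinv_gd(resid, pitch, inner_steps);
    }
  }

  for (int k = 0; k < order.size(); ++k) {
    const int v = order[k];
    const double c = std::cos(angles[v]), sn = std::sin(angles[v]);
    if (per_view) {
      for (int u = 0; u < U; ++u)
        ax[u] = joseph_ray(x.begin(), gm, c, sn, det_t(gm, u));
      if (differential) {
        std::vector<double> dax(U);
        drow(ax.data(), dax.data(), U, pitch);
        for (int u = 0; u < U; ++u) dax[u] = b(v, u) - dax[u];
        if (inner_mode == 1) {
          dinv_cum_row(dax.data(), e.data(), U, pitch);
        } else if (inner_mode == 2) {
          for (int u = 0; u < U; ++u) e[u] = e_state(v, u);
          dinv_gd_anchored_row(dax.data(), e.data(), U, pitch, inner_steps);
          for (int u = 0; u < U; ++u) e_state(v, u) = e[u];
        } else {
          dinv_gd_row(dax.data(), e.data(), U, pitch, inner_steps);
        }
        for (int u = 0; u < U; ++u) res += dax[u] * dax[u];
      } else {
        for (int u = 0; u < U; ++u) e[u] = b(v, u) - ax[u];
        for (int u = 0; u < U; ++u) res += e[u] * e[u];
      }
    } else {
      for (int u = 0; u < U; ++u) e[u] = e_all(v, u);
    }
    for (int u = 0; u < U; ++u) {
      const double rs = rowsum(v, u);
      r[u] = (rs > 1e-12) ? e[u] / rs : 0.0;
    }
    sart_view_update(x.begin(), nullptr, gm, c, sn, r.data(), nullptr, relax);
  }
  return List::create(_["x"] = x, _["res"] = std::sqrt(res));
}
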