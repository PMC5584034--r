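#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Smoothed anisotropic-root TV: sum over voxels of
// sqrt(dx^2 + dy^2 + dz^2 + eps) of forward differences (zero at far
// edges), with optional gradient. `b` is an optional second volume; when
// given, the TV of (a - b) is computed (difference images for the PIC and
// chain terms) without materializing the difference.

// [[Rcpp::export]]
List cpp_tv(NumericVector a, Nullable<NumericVector> b, IntegerVector dims,
            double eps, bool gradient) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double* A = a.begin();
  const double* B = nullptr;
  NumericVector bv;
  if (b.isNotNull()) {
    bv = b.get();
    B = bv.begin();
  }
  std::vector<double> d(n);
  if (B) for (R_xlen_t i = 0; i < n; ++i) d[i] = A[i] - B[i];
  else   for (R_xlen_t i = 0; i < n; ++i) d[i] = A[i];

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double value = 0.0;
  NumericVector grad;
  double* G = nullptr;
  std::vector<double> rx, ry, rz;   // per-voxel diff / root, for the adjoint
  if (gradient) {
    grad = NumericVector(n);
    G = grad.begin();
    rx.assign(n, 0.0); ry.assign(n, 0.0); rz.assign(n, 0.0);
  }

  R_xlen_t lin = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++lin) {
        const double v = d[lin];
        const double dx = (i < nx - 1) ? v - d[lin + sx] : 0.0;
        const double dy = (j < ny - 1) ? v - d[lin + sy] : 0.0;
        const double dz = (k < nz - 1) ? v - d[lin + sz] : 0.0;
        const double root = std::sqrt(dx * dx + dy * dy + dz * dz + eps);
        value += root;
        if (G) {
          const double inv = 1.0 / std::max(root, 1e-300);
          const double gx = dx * inv, gy = dy * inv, gz = dz * inv;
          G[lin] += gx + gy + gz;
          if (i < nx - 1) rx[lin] = gx;
          if (j < ny - 1) ry[lin] = gy;
          if (k < nz - 1) rz[lin] = gz;
        }
      }
    }
  }
  if (G) {
    lin = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++lin) {
          if (i > 0) G[lin] -= rx[lin - sx];
          if (j > 0) G[lin] -= ry[lin - sy];
          if (k > 0) G[lin] -= rz[lin - sz];
        }
  }
  if (gradient) return List::create(Named("value") = value,
                                    Named("gradient") = grad);
  return List::create(Named("value") = value);
}
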