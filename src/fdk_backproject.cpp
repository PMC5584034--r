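#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel-driven weighted backprojection for FDK.
// Frames are ramp-filtered projections resampled conceptually on a virtual
// detector plane through the isocenter, perpendicular to the per-view beam
// axis. det0 is the (row 0, col 0) cell center on that plane, eu/ev the
// column/row step vectors, axis the unit beam direction (source -> isocenter).
// Each voxel accumulates (SAD/dist)^2 * bilinear(frame; u, v).

// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector frames, int det_rows, int det_cols,
                                  IntegerVector dims, NumericVector vox,
                                  NumericVector origin, NumericMatrix src,
                                  NumericMatrix det0, NumericMatrix eu,
                                  NumericMatrix ev, NumericMatrix axis,
                                  double sad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nviews = src.ncol();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* V = out.begin();
  const double* F = frames.begin();

  for (int v = 0; v < nviews; ++v) {
    const double S[3] = {src(0, v), src(1, v), src(2, v)};
    const double D0[3] = {det0(0, v), det0(1, v), det0(2, v)};
    const double EU[3] = {eu(0, v), eu(1, v), eu(2, v)};
    const double EV[3] = {ev(0, v), ev(1, v), ev(2, v)};
    const double AX[3] = {axis(0, v), axis(1, v), axis(2, v)};
    const double eu2 = EU[0] * EU[0] + EU[1] * EU[1] + EU[2] * EU[2];
    const double ev2 = EV[0] * EV[0] + EV[1] * EV[1] + EV[2] * EV[2];
    const double* frame = F + (R_xlen_t)v * det_rows * det_cols;

    R_xlen_t lin = 0;
    for (int k = 0; k < nz; ++k) {
      const double z = origin[2] + (k + 0.5) * vox[2];
      for (int j = 0; j < ny; ++j) {
        const double y = origin[1] + (j + 0.5) * vox[1];
        for (int i = 0; i < nx; ++i, ++lin) {
          const double x = origin[0] + (i + 0.5) * vox[0];
          const double w0 = x - S[0], w1 = y - S[1], w2 = z - S[2];
          const double dist = w0 * AX[0] + w1 * AX[1] + w2 * AX[2];
          if (dist <= 1e-6) continue;
          const double sc = sad / dist;
          // intersection with the isocenter plane, relative to det0
          const double p0 = S[0] + sc * w0 - D0[0];
          const double p1 = S[1] + sc * w1 - D0[1];
          const double p2 = S[2] + sc * w2 - D0[2];
          const double uc = (p0 * EU[0] + p1 * EU[1] + p2 * EU[2]) / eu2;
          const double vr = (p0 * EV[0] + p1 * EV[1] + p2 * EV[2]) / ev2;
          if (uc < 0.0 || uc > det_cols - 1.0 || vr < 0.0 || vr > det_rows - 1.0)
            continue;
          int c0 = (int)std::floor(uc), r0 = (int)std::floor(vr);
          if (c0 > det_cols - 2) c0 = det_cols - 2;
          if (r0 > det_rows - 2) r0 = det_rows - 2;
          if (c0 < 0) c0 = 0;
          if (r0 < 0) r0 = 0;
          const double fu = uc - c0, fv = vr - r0;
          const double* col0 = frame + (R_xlen_t)c0 * det_rows;
          const double* col1 = col0 + det_rows;
          const double val =
              (1.0 - fu) * ((1.0 - fv) * col0[r0] + fv * col0[r0 + 1]) +
              fu * ((1.0 - fv) * col1[r0] + fv * col1[r0 + 1]);
          V[lin] += sc * sc * val;
        }
      }
    }
  }
  return out;
}
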