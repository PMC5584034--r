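#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Incremental Siddon traversal of one ray from S to P through a regular grid.
// Calls `body(linear_index, length_mm)` for every intersected voxel.
// Grid: corner `org` (mm), voxel sizes `vox` (mm), dims nx,ny,nz, cell-centered.
// Ties at voxel corners: the axis with the smaller parametric step advances
// first (x before y before z on exact equality) -- deterministic.
template <typename Body>
static inline void traverse_ray(const double* S, const double* P,
                                const double* org, const double* vox,
                                const int nx, const int ny, const int nz,
                                Body body) {
  const double D[3] = {P[0] - S[0], P[1] - S[1], P[2] - S[2]};
  const double len = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
  if (len <= 0.0) return;
  const int n[3] = {nx, ny, nz};
  const double INF = std::numeric_limits<double>::infinity();

  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    const double lo = org[a], hi = org[a] + n[a] * vox[a];
    if (D[a] == 0.0) {
      if (S[a] <= lo || S[a] >= hi) return;  // parallel outside slab
    } else {
      double t0 = (lo - S[a]) / D[a];
      double t1 = (hi - S[a]) / D[a];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > tmin) tmin = t0;
      if (t1 < tmax) tmax = t1;
    }
  }
  if (tmin >= tmax) return;

  // entry voxel from a point nudged inside
  double t = tmin;
  int idx[3];
  for (int a = 0; a < 3; ++a) {
    const double x = S[a] + (t + 1e-12) * D[a];
    int i = (int)std::floor((x - org[a]) / vox[a]);
    if (i < 0) i = 0;
    if (i >= n[a]) i = n[a] - 1;
    idx[a] = i;
  }
  // parametric step per crossed plane and t of next crossing, per axis
  double tnext[3], dt[3];
  int istep[3];
  for (int a = 0; a < 3; ++a) {
    if (D[a] == 0.0) {
      tnext[a] = INF; dt[a] = INF; istep[a] = 0;
    } else {
      dt[a] = vox[a] / std::fabs(D[a]);
      istep[a] = (D[a] > 0.0) ? 1 : -1;
      const int plane = idx[a] + (D[a] > 0.0 ? 1 : 0);
      tnext[a] = (org[a] + plane * vox[a] - S[a]) / D[a];
      if (tnext[a] < t) tnext[a] = t;
    }
  }
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  long lin = idx[0] * sx + idx[1] * sy + idx[2] * sz;

  while (t < tmax) {
    int a = 0;  // axis of smallest next crossing; x wins ties, then y
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    double tn = tnext[a];
    if (tn > tmax) tn = tmax;
    if (tn > t) body(lin, (tn - t) * len);
    t = tn;
    if (t >= tmax) break;
    idx[a] += istep[a];
    if (idx[a] < 0 || idx[a] >= n[a]) break;
    lin += istep[a] * (a == 0 ? sx : (a == 1 ? sy : sz));
    tnext[a] += dt[a];
  }
}

// Detector cell (r, c) center (0-based): det0 + c*eu + r*ev.
// src: 3 x nviews; det0/eu/ev: 3 x nviews.

// [[Rcpp::export]]
NumericVector cpp_siddon_forward(NumericVector vol, IntegerVector dims,
                                 NumericVector vox, NumericVector origin,
                                 NumericMatrix src, NumericMatrix det0,
                                 NumericMatrix eu, NumericMatrix ev,
                                 int det_rows, int det_cols) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nviews = src.ncol();
  const double* V = vol.begin();
  const double org[3] = {origin[0], origin[1], origin[2]};
  const double vx[3] = {vox[0], vox[1], vox[2]};
  NumericVector out((R_xlen_t)det_rows * det_cols * nviews);
  double* O = out.begin();

  for (int v = 0; v < nviews; ++v) {
    const double S[3] = {src(0, v), src(1, v), src(2, v)};
    const double D0[3] = {det0(0, v), det0(1, v), det0(2, v)};
    const double EU[3] = {eu(0, v), eu(1, v), eu(2, v)};
    const double EV[3] = {ev(0, v), ev(1, v), ev(2, v)};
    double* frame = O + (R_xlen_t)v * det_rows * det_cols;
    for (int c = 0; c < det_cols; ++c) {
      double base[3] = {D0[0] + c * EU[0], D0[1] + c * EU[1], D0[2] + c * EU[2]};
      for (int r = 0; r < det_rows; ++r) {
        const double P[3] = {base[0] + r * EV[0], base[1] + r * EV[1],
                             base[2] + r * EV[2]};
        double acc = 0.0;
        traverse_ray(S, P, org, vx, nx, ny, nz,
                     [&](long lin, double l) { acc += V[lin] * l; });
        frame[(R_xlen_t)c * det_rows + r] = acc;
      }
    }
  }
  return out;
}

// Exact adjoint of cpp_siddon_forward (same traversal, scatter instead of gather).

// [[Rcpp::export]]
NumericVector cpp_siddon_back(NumericVector proj, IntegerVector dims,
                              NumericVector vox, NumericVector origin,
                              NumericMatrix src, NumericMatrix det0,
                              NumericMatrix eu, NumericMatrix ev,
                              int det_rows, int det_cols) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nviews = src.ncol();
  const double org[3] = {origin[0], origin[1], origin[2]};
  const double vx[3] = {vox[0], vox[1], vox[2]};
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* V = out.begin();
  const double* P0 = proj.begin();

  for (int v = 0; v < nviews; ++v) {
    const double S[3] = {src(0, v), src(1, v), src(2, v)};
    const double D0[3] = {det0(0, v), det0(1, v), det0(2, v)};
    const double EU[3] = {eu(0, v), eu(1, v), eu(2, v)};
    const double EV[3] = {ev(0, v), ev(1, v), ev(2, v)};
    const double* frame = P0 + (R_xlen_t)v * det_rows * det_cols;
    for (int c = 0; c < det_cols; ++c) {
      double base[3] = {D0[0] + c * EU[0], D0[1] + c * EU[1], D0[2] + c * EU[2]};
      for (int r = 0; r < det_rows; ++r) {
        const double y = frame[(R_xlen_t)c * det_rows + r];
        if (y == 0.0) continue;
        const double P[3] = {base[0] + r * EV[0], base[1] + r * EV[1],
                             base[2] + r * EV[2]};
        traverse_ray(S, P, org, vx, nx, ny, nz,
                     [&](long lin, double l) { V[lin] += y * l; });
      }
    }
  }
  return out;
}
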