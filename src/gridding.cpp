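// Kaiser-Bessel gridding kernels for the non-uniform FFT.
//
// Points are given in "fine-grid" units: u = k * G where k is the k-space
// coordinate in cycles/voxel and G the oversampled grid size, so one unit
// equals one cell of the oversampled frequency grid. Indices wrap modulo G
// (the oversampled DFT is periodic). The 1D kernel is read from a dense
// lookup table with linear interpolation.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double kb_lookup(double d, const NumericVector& table,
                               double half_width, int ntab) {
  double ad = std::fabs(d);
  if (ad >= half_width) return 0.0;
  double pos = ad / half_width * (ntab - 1);
  int i0 = static_cast<int>(pos);
  if (i0 >= ntab - 1) return table[ntab - 1];
  double frac = pos - i0;
  return table[i0] * (1.0 - frac) + table[i0 + 1] * frac;
}

struct NeighborWeights {
  int idx[3][8];     // wrapped grid indices per dimension
  double w[3][8];    // kernel weights per dimension
  int cnt[3];
};

static inline void neighbor_weights(const double* u, int G, int W,
                                    const NumericVector& table, int ntab,
                                    NeighborWeights& nw) {
  double half_width = W / 2.0;
  for (int d = 0; d < 3; ++d) {
    int start = static_cast<int>(std::ceil(u[d] - half_width));
    int c = 0;
    for (int j = start; j <= start + W; ++j) {
      double wt = kb_lookup(j - u[d], table, half_width, ntab);
      if (wt > 0.0) {
        int idx = j % G;
        if (idx < 0) idx += G;
        nw.idx[d][c] = idx;
        nw.w[d][c] = wt;
        ++c;
      }
    }
    nw.cnt[d] = c;
  }
}

// Interpolate oversampled-grid spectrum values at arbitrary fine-grid
// points (type-2 step of the forward NUFFT).
// [[Rcpp::export]]
ComplexVector kb_interpolate(ComplexVector grid, IntegerVector gdim,
                             NumericMatrix pts, int width,
                             NumericVector table) {
  const int G = gdim[0];
  if (gdim[1] != G || gdim[2] != G)
    stop("oversampled grid must be cubic");
  const int n = pts.nrow();
  const int ntab = table.size();
  ComplexVector out(n);
  const Rcomplex* g = grid.begin();
  NeighborWeights nw;
  for (int i = 0; i < n; ++i) {
    double u[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    neighbor_weights(u, G, width, table, ntab, nw);
    double re = 0.0, im = 0.0;
    for (int c2 = 0; c2 < nw.cnt[2]; ++c2) {
      const double w2 = nw.w[2][c2];
      const long off2 = static_cast<long>(nw.idx[2][c2]) * G * G;
      for (int c1 = 0; c1 < nw.cnt[1]; ++c1) {
        const double w12 = w2 * nw.w[1][c1];
        const long off1 = off2 + static_cast<long>(nw.idx[1][c1]) * G;
        for (int c0 = 0; c0 < nw.cnt[0]; ++c0) {
          const double w = w12 * nw.w[0][c0];
          const Rcomplex& z = g[off1 + nw.idx[0][c0]];
          re += w * z.r;
          im += w * z.i;
        }
      }
    }
    out[i].r = re;
    out[i].i = im;
  }
  return out;
}

// Spread sample values onto the oversampled grid with the same weights
// (exact adjoint of kb_interpolate).
// [[Rcpp::export]]
ComplexVector kb_spread(ComplexVector vals, IntegerVector gdim,
                        NumericMatrix pts, int width,
                        NumericVector table) {
  const int G = gdim[0];
  if (gdim[1] != G || gdim[2] != G)
    stop("oversampled grid must be cubic");
  const int n = pts.nrow();
  if (vals.size() != n) stop("length(vals) must equal nrow(pts)");
  const int ntab = table.size();
  ComplexVector out(static_cast<R_xlen_t>(G) * G * G);
  Rcomplex* g = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) { g[i].r = 0.0; g[i].i = 0.0; }
  NeighborWeights nw;
  for (int i = 0; i < n; ++i) {
    double u[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    neighbor_weights(u, G, width, table, ntab, nw);
    const double vr = vals[i].r, vi = vals[i].i;
    for (int c2 = 0; c2 < nw.cnt[2]; ++c2) {
      const double w2 = nw.w[2][c2];
      const long off2 = static_cast<long>(nw.idx[2][c2]) * G * G;
      for (int c1 = 0; c1 < nw.cnt[1]; ++c1) {
        const double w12 = w2 * nw.w[1][c1];
        const long off1 = off2 + static_cast<long>(nw.idx[1][c1]) * G;
        for (int c0 = 0; c0 < nw.cnt[0]; ++c0) {
          const double w = w12 * nw.w[0][c0];
          Rcomplex& z = g[off1 + nw.idx[0][c0]];
          z.r += w * vr;
          z.i += w * vi;
        }
      }
    }
  }
  return out;
}
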