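// Periodic trilinear map interpolation and residue proximity masks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int wrap(int i, int n) { return ((i % n) + n) % n; }

// Trilinear interpolation of a periodic unit-cell grid at fractional points.
// map: nx*ny*nz values, column-major (x fastest), point (i,j,k) at fractional
// (i/nx, j/ny, k/nz). pts: m x 3 fractional coordinates (any real values).
// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector& map,
                            int nx, int ny, int nz,
                            const arma::mat& pts) {
  const int m = pts.n_rows;
  NumericVector out(m);
  const double* g = REAL(map);
  for (int p = 0; p < m; ++p) {
    const double fx = pts(p,0) * nx, fy = pts(p,1) * ny, fz = pts(p,2) * nz;
    const int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
    const double tx = fx - ix, ty = fy - iy, tz = fz - iz;
    const int x0 = wrap(ix, nx), x1 = wrap(ix + 1, nx);
    const int y0 = wrap(iy, ny), y1 = wrap(iy + 1, ny);
    const int z0 = wrap(iz, nz), z1 = wrap(iz + 1, nz);
    #define G(i,j,k) g[(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
    const double c00 = G(x0,y0,z0) * (1-tx) + G(x1,y0,z0) * tx;
    const double c10 = G(x0,y1,z0) * (1-tx) + G(x1,y1,z0) * tx;
    const double c01 = G(x0,y0,z1) * (1-tx) + G(x1,y0,z1) * tx;
    const double c11 = G(x0,y1,z1) * (1-tx) + G(x1,y1,z1) * tx;
    #undef G
    const double c0 = c00 * (1-ty) + c10 * ty;
    const double c1 = c01 * (1-ty) + c11 * ty;
    out[p] = c0 * (1-tz) + c1 * tz;
  }
  return out;
}

// Logical mask over the unit-cell grid: TRUE where a grid point lies within
// `radius` AA of any of the given atom positions (periodic images included).
// [[Rcpp::export]]
LogicalVector cpp_mask_near_atoms(int nx, int ny, int nz,
                                  const arma::mat& orth,
                                  const arma::mat& frac,
                                  const arma::mat& coords,
                                  double radius) {
  LogicalVector out((R_xlen_t)nx * ny * nz);
  int* msk = LOGICAL(out);
  std::fill(msk, msk + out.size(), 0);
  arma::rowvec rn(3);
  for (int d = 0; d < 3; ++d) rn(d) = arma::norm(frac.row(d), 2);
  const double r2max = radius * radius;
  const int nn[3] = {nx, ny, nz};
  for (arma::uword a = 0; a < coords.n_rows; ++a) {
    arma::vec pos = coords.row(a).t();
    arma::vec fp = frac * pos;
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      const double df = radius * rn(d);
      lo[d] = (int)std::floor((fp(d) - df) * nn[d]) - 1;
      hi[d] = (int)std::ceil((fp(d) + df) * nn[d]) + 1;
    }
    for (int k = lo[2]; k <= hi[2]; ++k) {
      const int kw = wrap(k, nz);
      for (int j = lo[1]; j <= hi[1]; ++j) {
        const int jw = wrap(j, ny);
        const R_xlen_t base = (R_xlen_t)nx * (jw + (R_xlen_t)ny * kw);
        for (int i = lo[0]; i <= hi[0]; ++i) {
          const double gx = (double)i / nx, gy = (double)j / ny, gz = (double)k / nz;
          const double px = orth(0,0)*gx + orth(0,1)*gy + orth(0,2)*gz - pos(0);
          const double py = orth(1,0)*gx + orth(1,1)*gy + orth(1,2)*gz - pos(1);
          const double pz = orth(2,0)*gx + orth(2,1)*gy + orth(2,2)*gz - pos(2);
          if (px*px + py*py + pz*pz <= r2max) msk[wrap(i, nx) + base] = 1;
        }
      }
    }
  }
  return out;
}
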