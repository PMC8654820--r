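// Real-space Gaussian density synthesis and direct-summation structure factors.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Density of one atom at squared distance r2, from per-term amplitudes and
// decay constants (amp_i = occ * a_i * (4*pi/(B+b_i))^{3/2}, alpha_i =
// 4*pi^2/(B+b_i)).
static inline double gauss_sum(const double* amp, const double* alpha,
                               int nterm, double r2) {
  double v = 0.0;
  for (int i = 0; i < nterm; ++i) v += amp[i] * std::exp(-alpha[i] * r2);
  return v;
}

// Synthesize a P1 unit-cell density map by summing atomic Gaussians over all
// periodic images that contribute above a relative cutoff.
//
// coords: n x 3 orthogonal AA; occ, biso: length n; elem: 0-based column into
// amat/bmat (nterm x nelem); orth/frac: 3x3 orthogonalization and
// fractionalization matrices; cutoff_rel: terminate each atom's contribution
// where its density falls below cutoff_rel * peak.
// [[Rcpp::export]]
NumericVector cpp_synth_map(const arma::mat& coords,
                            const arma::vec& occ,
                            const arma::vec& biso,
                            const IntegerVector& elem,
                            const arma::mat& amat,
                            const arma::mat& bmat,
                            const arma::mat& orth,
                            const arma::mat& frac,
                            int nx, int ny, int nz,
                            double cutoff_rel) {
  const int natom = coords.n_rows;
  const int nterm = amat.n_rows;
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* map = REAL(out);
  const double fourpi = 4.0 * M_PI;
  const double fourpi2 = 4.0 * M_PI * M_PI;

  // row norms of frac: fractional half-widths per AA of cutoff radius
  arma::rowvec rn(3);
  for (int d = 0; d < 3; ++d) rn(d) = arma::norm(frac.row(d), 2);

  std::vector<double> amp(nterm), alpha(nterm);
  for (int a = 0; a < natom; ++a) {
    const int e = elem[a];
    double peak = 0.0;
    for (int i = 0; i < nterm; ++i) {
      const double beff = biso(a) + bmat(i, e);
      if (beff <= 0.0) stop("non-positive effective Gaussian width (B_iso + b_i); increase B_iso");
      amp[i] = occ(a) * amat(i, e) * std::pow(fourpi / beff, 1.5);
      alpha[i] = fourpi2 / beff;
      peak += amp[i];
    }
    if (peak <= 0.0) continue;
    const double floorv = cutoff_rel * peak;
    // conservative cutoff radius: max over terms of where |term| alone drops
    // below floorv / nterm
    double rc2 = 0.0;
    for (int i = 0; i < nterm; ++i) {
      const double aamp = std::abs(amp[i]);
      if (aamp <= 0.0) continue;
      const double arg = aamp * nterm / floorv;
      if (arg > 1.0) {
        const double r2 = std::log(arg) / alpha[i];
        if (r2 > rc2) rc2 = r2;
      }
    }
    const double rc = std::sqrt(rc2);
    arma::vec pos = coords.row(a).t();
    arma::vec fp = frac * pos;
    // grid index ranges (unwrapped) covering the cutoff sphere
    int lo[3], hi[3];
    const int nn[3] = {nx, ny, nz};
    for (int d = 0; d < 3; ++d) {
      const double df = rc * rn(d);
      lo[d] = (int)std::floor((fp(d) - df) * nn[d]) - 1;
      hi[d] = (int)std::ceil((fp(d) + df) * nn[d]) + 1;
      if (hi[d] - lo[d] + 1 > 4 * nn[d] + 8) {
        // cutoff sphere spans many cells; clamp to a full period around atom
        lo[d] = (int)std::floor(fp(d) * nn[d]) - 2 * nn[d];
        hi[d] = lo[d] + 4 * nn[d];
      }
    }
    for (int k = lo[2]; k <= hi[2]; ++k) {
      const int kw = ((k % nz) + nz) % nz;
      for (int j = lo[1]; j <= hi[1]; ++j) {
        const int jw = ((j % ny) + ny) % ny;
        const R_xlen_t base = (R_xlen_t)nx * (jw + (R_xlen_t)ny * kw);
        for (int i = lo[0]; i <= hi[0]; ++i) {
          // Cartesian position of unwrapped grid point
          const double gx = (double)i / nx, gy = (double)j / ny, gz = (double)k / nz;
          const double px = orth(0,0)*gx + orth(0,1)*gy + orth(0,2)*gz - pos(0);
          const double py = orth(1,0)*gx + orth(1,1)*gy + orth(1,2)*gz - pos(1);
          const double pz = orth(2,0)*gx + orth(2,1)*gy + orth(2,2)*gz - pos(2);
          const double r2 = px*px + py*py + pz*pz;
          if (r2 > rc2) continue;
          const int iw = ((i % nx) + nx) % nx;
          map[iw + base] += gauss_sum(amp.data(), alpha.data(), nterm, r2);
        }
      }
    }
  }
  return out;
}

// Direct-summation structure factors for a P1 cell.
// fcoords: n x 3 fractional coordinates; q2: squared reciprocal distance
// 1/d^2 per reflection; hkl: m x 3 (double-valued integers).
// F(h) = sum_atoms occ * [ sum_i a_i exp(-(b_i + B) q^2 / 4) ] * exp(2 pi i h.x)
// [[Rcpp::export]]
ComplexVector cpp_structure_factors(const arma::mat& hkl,
                                    const arma::vec& q2,
                                    const arma::mat& fcoords,
                                    const arma::vec& occ,
                                    const arma::vec& biso,
                                    const IntegerVector& elem,
                                    const arma::mat& amat,
                                    const arma::mat& bmat) {
  const int m = hkl.n_rows;
  const int natom = fcoords.n_rows;
  const int nterm = amat.n_rows;
  ComplexVector out(m);
  const double twopi = 2.0 * M_PI;
  for (int j = 0; j < m; ++j) {
    const double h = hkl(j,0), k = hkl(j,1), l = hkl(j,2);
    const double q24 = q2(j) / 4.0;
    double fre = 0.0, fim = 0.0;
    for (int a = 0; a < natom; ++a) {
      const int e = elem[a];
      double f = 0.0;
      for (int i = 0; i < nterm; ++i)
        f += amat(i,e) * std::exp(-(bmat(i,e) + biso(a)) * q24);
      f *= occ(a);
      const double ph = twopi * (h * fcoords(a,0) + k * fcoords(a,1) + l * fcoords(a,2));
      fre += f * std::cos(ph);
      fim += f * std::sin(ph);
    }
    out[j].r = fre;
    out[j].i = fim;
  }
  return out;
}
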