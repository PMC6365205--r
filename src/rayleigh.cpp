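#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct Rayleigh-Sommerfeld (first integral) summation of baffled point
// sub-sources: p(r) = sum_j a_j * exp(i k R_j) / R_j, with a_j the complex
// source strength (-i omega rho v_n dS / (2 pi)) supplied from R.
// Positions in meters, k in rad/m.

// [[Rcpp::export]]
ComplexVector rs_field_cpp(NumericMatrix src, ComplexVector amp,
                           NumericMatrix pts, double k) {
  const int ns = src.nrow(), np = pts.nrow();
  ComplexVector out(np);
  std::vector<double> re(np, 0.0), im(np, 0.0);
  for (int j = 0; j < ns; ++j) {
    const double sx = src(j, 0), sy = src(j, 1), sz = src(j, 2);
    const double ar = amp[j].r, ai = amp[j].i;
    for (int p = 0; p < np; ++p) {
      const double dx = pts(p, 0) - sx, dy = pts(p, 1) - sy,
                   dz = pts(p, 2) - sz;
      const double R = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double c = std::cos(k * R) / R, s = std::sin(k * R) / R;
      re[p] += ar * c - ai * s;
      im[p] += ar * s + ai * c;
    }
  }
  for (int p = 0; p < np; ++p) {
    out[p].r = re[p];
    out[p].i = im[p];
  }
  return out;
}

// Per-element Rayleigh-Sommerfeld responses: returns an n_elem x n_pts
// complex matrix (the ERFA), elem gives the 1-based element id of each
// sub-source row of src.

// [[Rcpp::export]]
ComplexMatrix rs_erfa_cpp(NumericMatrix src, ComplexVector amp,
                          IntegerVector elem, int n_elem,
                          NumericMatrix pts, double k) {
  const int ns = src.nrow(), np = pts.nrow();
  std::vector<double> re((size_t)n_elem * np, 0.0),
                      im((size_t)n_elem * np, 0.0);
  for (int j = 0; j < ns; ++j) {
    const double sx = src(j, 0), sy = src(j, 1), sz = src(j, 2);
    const double ar = amp[j].r, ai = amp[j].i;
    const size_t e = (size_t)(elem[j] - 1);
    double *rr = &re[e * np], *ii = &im[e * np];
    for (int p = 0; p < np; ++p) {
      const double dx = pts(p, 0) - sx, dy = pts(p, 1) - sy,
                   dz = pts(p, 2) - sz;
      const double R = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double c = std::cos(k * R) / R, s = std::sin(k * R) / R;
      rr[p] += ar * c - ai * s;
      ii[p] += ar * s + ai * c;
    }
  }
  ComplexMatrix out(n_elem, np);
  for (int e = 0; e < n_elem; ++e)
    for (int p = 0; p < np; ++p) {
      out(e, p).r = re[(size_t)e * np + p];
      out(e, p).i = im[(size_t)e * np + p];
    }
  return out;
}
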