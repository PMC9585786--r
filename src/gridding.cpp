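#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

// Kaiser-Bessel kernel, width W in (oversampled) grid cells, shape beta.
// Evaluated through a dense lookup table with linear interpolation:
// R::bessel_i is far too slow to call per neighbour per sample.
struct KbLut {
  std::vector<double> tab;
  double halfwidth;
  double scale;  // entries per unit distance
  KbLut(double hw, double beta) : halfwidth(hw) {
    const int nent = 8192;
    const double i0beta = R::bessel_i(beta, 0.0, 1.0);
    tab.resize(nent + 2);
    for (int i = 0; i <= nent; ++i) {
      double d = hw * i / nent;
      double arg = 1.0 - (d / hw) * (d / hw);
      tab[i] = (arg <= 0.0) ? 0.0
        : R::bessel_i(beta * std::sqrt(arg), 0.0, 1.0) / i0beta;
    }
    tab[nent + 1] = 0.0;
    scale = nent / hw;
  }
  inline double operator()(double d) const {
    d = std::fabs(d);
    if (d >= halfwidth) return 0.0;
    double u = d * scale;
    int i = (int)u;
    double f = u - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }
};

static inline int wrap_index(int i, int n) {
  int r = i % n;
  return (r < 0) ? r + n : r;
}

// Adjoint gridding: scatter weighted k-space samples onto a periodic
// Cartesian grid of size n^3. coords are 0-based fractional grid indices.
// [[Rcpp::export]]
ComplexVector kb_grid_adjoint(NumericMatrix coords, ComplexVector data,
                              int n, double width, double beta) {
  const int ns = coords.nrow();
  if (data.size() != ns) stop("coords/data length mismatch");
  const double hw = width / 2.0;
  const KbLut kb(hw, beta);
  std::vector<std::complex<double> > grid((size_t)n * n * n,
                                          std::complex<double>(0.0, 0.0));
  for (int s = 0; s < ns; ++s) {
    const double u = coords(s, 0), v = coords(s, 1), w = coords(s, 2);
    const std::complex<double> val(data[s].r, data[s].i);
    const int iu0 = (int)std::ceil(u - hw), iu1 = (int)std::floor(u + hw);
    const int iv0 = (int)std::ceil(v - hw), iv1 = (int)std::floor(v + hw);
    const int iw0 = (int)std::ceil(w - hw), iw1 = (int)std::floor(w + hw);
    for (int iw_ = iw0; iw_ <= iw1; ++iw_) {
      const double kz = kb(w - iw_);
      if (kz == 0.0) continue;
      const int zi = wrap_index(iw_, n);
      for (int iv_ = iv0; iv_ <= iv1; ++iv_) {
        const double ky = kb(v - iv_);
        if (ky == 0.0) continue;
        const int yi = wrap_index(iv_, n);
        const double kyz = ky * kz;
        for (int iu_ = iu0; iu_ <= iu1; ++iu_) {
          const double kx = kb(u - iu_);
          if (kx == 0.0) continue;
          const int xi = wrap_index(iu_, n);
          grid[(size_t)zi * n * n + (size_t)yi * n + xi] += val * (kx * kyz);
        }
      }
    }
  }
  ComplexVector out((size_t)n * n * n);
  for (size_t i = 0; i < grid.size(); ++i) {
    out[i].r = grid[i].real();
    out[i].i = grid[i].imag();
  }
  return out;
}

// Forward interpolation: gather periodic Cartesian grid values at
// non-Cartesian sample locations (0-based fractional grid indices).
// [[Rcpp::export]]
ComplexVector kb_interp_forward(ComplexVector grid, int n,
                                NumericMatrix coords, double width,
                                double beta) {
  if (grid.size() != (R_xlen_t)n * n * n) stop("grid size mismatch");
  const int ns = coords.nrow();
  const double hw = width / 2.0;
  const KbLut kb(hw, beta);
  ComplexVector out(ns);
  for (int s = 0; s < ns; ++s) {
    const double u = coords(s, 0), v = coords(s, 1), w = coords(s, 2);
    std::complex<double> acc(0.0, 0.0);
    const int iu0 = (int)std::ceil(u - hw), iu1 = (int)std::floor(u + hw);
    const int iv0 = (int)std::ceil(v - hw), iv1 = (int)std::floor(v + hw);
    const int iw0 = (int)std::ceil(w - hw), iw1 = (int)std::floor(w + hw);
    for (int iw_ = iw0; iw_ <= iw1; ++iw_) {
      const double kz = kb(w - iw_);
      if (kz == 0.0) continue;
      const int zi = wrap_index(iw_, n);
      for (int iv_ = iv0; iv_ <= iv1; ++iv_) {
        const double ky = kb(v - iv_);
        if (ky == 0.0) continue;
        const int yi = wrap_index(iv_, n);
        const double kyz = ky * kz;
        for (int iu_ = iu0; iu_ <= iu1; ++iu_) {
          const double kx = kb(u - iu_);
          if (kx == 0.0) continue;
          const int xi = wrap_index(iu_, n);
          const Rcomplex g = grid[(size_t)zi * n * n + (size_t)yi * n + xi];
          acc += std::complex<double>(g.r, g.i) * (kx * kyz);
        }
      }
    }
    out[s].r = acc.real();
    out[s].i = acc.imag();
  }
  return out;
}

// Direct (slow) discrete Fourier sum: psf(x) = sum_j w_j exp(2*pi*i k_j . x).
// Exact adjoint NDFT used for small point-spread-function grids.
// [[Rcpp::export]]
ComplexVector ndft_adjoint(NumericMatrix kcoords, ComplexVector weights,
                           NumericMatrix xcoords) {
  const int ns = kcoords.nrow();
  if (weights.size() != ns) stop("kcoords/weights length mismatch");
  const int np = xcoords.nrow();
  const double twopi = 2.0 * M_PI;
  ComplexVector out(np);
  for (int p = 0; p < np; ++p) {
    const double x = xcoords(p, 0), y = xcoords(p, 1), z = xcoords(p, 2);
    std::complex<double> acc(0.0, 0.0);
    for (int j = 0; j < ns; ++j) {
      const double ph = twopi * (kcoords(j, 0) * x + kcoords(j, 1) * y +
                                 kcoords(j, 2) * z);
      acc += std::complex<double>(weights[j].r, weights[j].i) *
             std::complex<double>(std::cos(ph), std::sin(ph));
    }
    out[p].r = acc.real();
    out[p].i = acc.imag();
  }
  return out;
}
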