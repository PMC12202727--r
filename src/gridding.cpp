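#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kaiser-Bessel kernel value at offset u (grid units), support |u| < W/2.
static inline double kb(double u, double W, double beta) {
  double t = 2.0 * u / W;
  double arg = 1.0 - t * t;
  if (arg <= 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(arg), 0.0, 1.0);
}

// Spread weighted complex samples onto a 2D oversampled k-space grid.
// coords: n x 2 continuous 1-based grid indices; dims: c(nx, ny).
// [[Rcpp::export]]
ComplexVector kb_grid2(NumericMatrix coords, ComplexVector data,
                       NumericVector weights, IntegerVector dims,
                       double W, double beta) {
  int nx = dims[0], ny = dims[1], n = coords.nrow();
  ComplexVector out(nx * ny);
  double half = W / 2.0;
  for (int i = 0; i < n; ++i) {
    double px = coords(i, 0), py = coords(i, 1);
    double re = data[i].r * weights[i], im = data[i].i * weights[i];
    int x0 = (int)std::ceil(px - half), x1 = (int)std::floor(px + half);
    int y0 = (int)std::ceil(py - half), y1 = (int)std::floor(py + half);
    for (int y = y0; y <= y1; ++y) {
      if (y < 1 || y > ny) continue;
      double wy = kb(y - py, W, beta);
      if (wy == 0.0) continue;
      for (int x = x0; x <= x1; ++x) {
        if (x < 1 || x > nx) continue;
        double w = wy * kb(x - px, W, beta);
        if (w == 0.0) continue;
        int idx = (x - 1) + nx * (y - 1);
        out[idx].r += re * w;
        out[idx].i += im * w;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector kb_grid3(NumericMatrix coords, ComplexVector data,
                       NumericVector weights, IntegerVector dims,
                       double W, double beta) {
  int nx = dims[0], ny = dims[1], nz = dims[2], n = coords.nrow();
  ComplexVector out((R_xlen_t)nx * ny * nz);
  double half = W / 2.0;
  for (int i = 0; i < n; ++i) {
    double px = coords(i, 0), py = coords(i, 1), pz = coords(i, 2);
    double re = data[i].r * weights[i], im = data[i].i * weights[i];
    int x0 = (int)std::ceil(px - half), x1 = (int)std::floor(px + half);
    int y0 = (int)std::ceil(py - half), y1 = (int)std::floor(py + half);
    int z0 = (int)std::ceil(pz - half), z1 = (int)std::floor(pz + half);
    for (int z = z0; z <= z1; ++z) {
      if (z < 1 || z > nz) continue;
      double wz = kb(z - pz, W, beta);
      if (wz == 0.0) continue;
      for (int y = y0; y <= y1; ++y) {
        if (y < 1 || y > ny) continue;
        double wyz = wz * kb(y - py, W, beta);
        if (wyz == 0.0) continue;
        for (int x = x0; x <= x1; ++x) {
          if (x < 1 || x > nx) continue;
          double w = wyz * kb(x - px, W, beta);
          if (w == 0.0) continue;
          R_xlen_t idx = (x - 1) + (R_xlen_t)nx * ((y - 1) + (R_xlen_t)ny * (z - 1));
          out[idx].r += re * w;
          out[idx].i += im * w;
        }
      }
    }
  }
  return out;
}

// Interpolate a gridded k-space back onto non-Cartesian coordinates
// (forward NUFFT sampling step; exact adjoint of kb_grid* with unit weights).
// [[Rcpp::export]]
ComplexVector kb_interp2(ComplexVector grid, NumericMatrix coords,
                         IntegerVector dims, double W, double beta) {
  int nx = dims[0], ny = dims[1], n = coords.nrow();
  ComplexVector out(n);
  double half = W / 2.0;
  for (int i = 0; i < n; ++i) {
    double px = coords(i, 0), py = coords(i, 1);
    double re = 0.0, im = 0.0;
    int x0 = (int)std::ceil(px - half), x1 = (int)std::floor(px + half);
    int y0 = (int)std::ceil(py - half), y1 = (int)std::floor(py + half);
    for (int y = y0; y <= y1; ++y) {
      if (y < 1 || y > ny) continue;
      double wy = kb(y - py, W, beta);
      if (wy == 0.0) continue;
      for (int x = x0; x <= x1; ++x) {
        if (x < 1 || x > nx) continue;
        double w = wy * kb(x - px, W, beta);
        int idx = (x - 1) + nx * (y - 1);
        re += grid[idx].r * w;
        im += grid[idx].i * w;
      }
    }
    out[i].r = re;
    out[i].i = im;
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector kb_interp3(ComplexVector grid, NumericMatrix coords,
                         IntegerVector dims, double W, double beta) {
  int nx = dims[0], ny = dims[1], nz = dims[2], n = coords.nrow();
  ComplexVector out(n);
  double half = W / 2.0;
  for (int i = 0; i < n; ++i) {
    double px = coords(i, 0), py = coords(i, 1), pz = coords(i, 2);
    double re = 0.0, im = 0.0;
    int x0 = (int)std::ceil(px - half), x1 = (int)std::floor(px + half);
    int y0 = (int)std::ceil(py - half), y1 = (int)std::floor(py + half);
    int z0 = (int)std::ceil(pz - half), z1 = (int)std::floor(pz + half);
    for (int z = z0; z <= z1; ++z) {
      if (z < 1 || z > nz) continue;
      double wz = kb(z - pz, W, beta);
      if (wz == 0.0) continue;
      for (int y = y0; y <= y1; ++y) {
        if (y < 1 || y > ny) continue;
        double wyz = wz * kb(y - py, W, beta);
        if (wyz == 0.0) continue;
        for (int x = x0; x <= x1; ++x) {
          if (x < 1 || x > nx) continue;
          double w = wyz * kb(x - px, W, beta);
          R_xlen_t idx = (x - 1) + (R_xlen_t)nx * ((y - 1) + (R_xlen_t)ny * (z - 1));
          re += grid[idx].r * w;
          im += grid[idx].i * w;
        }
      }
    }
    out[i].r = re;
    out[i].i = im;
  }
  return out;
}

// Sum of Gaussian void terms in k-space at one time instant:
//   sum_p pref[p] * exp(-decay[p] * |k|^2) * exp(-2*pi*i * k . pos_p)
// k: n x d (cycles/mm), pos: np x d (mm).
// [[Rcpp::export]]
ComplexVector void_kspace_sum(NumericMatrix k, NumericMatrix pos,
                              NumericVector pref, NumericVector decay) {
  int n = k.nrow(), d = k.ncol(), np = pos.nrow();
  ComplexVector out(n);
  const double twopi = 2.0 * M_PI;
  for (int i = 0; i < n; ++i) {
    double k2 = 0.0;
    for (int c = 0; c < d; ++c) k2 += k(i, c) * k(i, c);
    double re = 0.0, im = 0.0;
    for (int p = 0; p < np; ++p) {
      double amp = pref[p] * std::exp(-decay[p] * k2);
      double ph = 0.0;
      for (int c = 0; c < d; ++c) ph += k(i, c) * pos(p, c);
      ph *= -twopi;
      re += amp * std::cos(ph);
      im += amp * std::sin(ph);
    }
    out[i].r = re;
    out[i].i = im;
  }
  return out;
}
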