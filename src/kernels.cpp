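#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3-D volume at continuous voxel coordinates.
// `coords` is n x 3, 0-based voxel units. Samples falling outside the grid
// contribute 0 (volumes are zero-padded by convention: background is air).
// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector vol, NumericMatrix coords) {
  IntegerVector dim = vol.attr("dim");
  if (dim.size() != 3) stop("volume must be a 3-D array");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = coords.nrow();
  const double *v = REAL(vol);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
      const int zi = z0 + dz;
      if (zi < 0 || zi >= nz) continue;
      const double wz = dz ? fz : 1.0 - fz;
      for (int dy = 0; dy < 2; ++dy) {
        const int yi = y0 + dy;
        if (yi < 0 || yi >= ny) continue;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx < 2; ++dx) {
          const int xi = x0 + dx;
          if (xi < 0 || xi >= nx) continue;
          const double wx = dx ? fx : 1.0 - fx;
          acc += wx * wy * wz *
                 v[(size_t)xi + (size_t)nx * ((size_t)yi + (size_t)ny * zi)];
        }
      }
    }
    out[i] = acc;
  }
  return out;
}

// Adjoint of trilinear_sample: scatter `vals` into the accumulator array
// `acc` (modified in place; callers allocate it fresh). Out-of-grid samples
// are dropped, mirroring the zero-padding of the sampler.
// [[Rcpp::export(name = ".trilinear_splat")]]
void trilinear_splat(NumericVector acc, NumericMatrix coords,
                     NumericVector vals) {
  IntegerVector dim = acc.attr("dim");
  if (dim.size() != 3) stop("accumulator must be a 3-D array");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = coords.nrow();
  if (vals.size() != n) stop("vals length must match coords rows");
  double *a = REAL(acc);
  for (int i = 0; i < n; ++i) {
    const double val = vals[i];
    if (val == 0.0) continue;
    const double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    for (int dz = 0; dz < 2; ++dz) {
      const int zi = z0 + dz;
      if (zi < 0 || zi >= nz) continue;
      const double wz = dz ? fz : 1.0 - fz;
      for (int dy = 0; dy < 2; ++dy) {
        const int yi = y0 + dy;
        if (yi < 0 || yi >= ny) continue;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx < 2; ++dx) {
          const int xi = x0 + dx;
          if (xi < 0 || xi >= nx) continue;
          const double wx = dx ? fx : 1.0 - fx;
          a[(size_t)xi + (size_t)nx * ((size_t)yi + (size_t)ny * zi)] +=
              wx * wy * wz * val;
        }
      }
    }
  }
}
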