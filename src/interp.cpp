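#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear / tricubic (Catmull-Rom) sampling of a 3D scalar grid at
// continuous 0-based voxel coordinates.  Out-of-grid coordinates take the
// nearest-edge (replicate) value and are flagged.

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline void cr_weights(double u, double w[4]) {
  // Catmull-Rom (cubic convolution, a = -1/2); exact for quadratics.
  double u2 = u * u, u3 = u2 * u;
  w[0] = -0.5 * u3 + u2 - 0.5 * u;
  w[1] =  1.5 * u3 - 2.5 * u2 + 1.0;
  w[2] = -1.5 * u3 + 2.0 * u2 + 0.5 * u;
  w[3] =  0.5 * u3 - 0.5 * u2;
}

// [[Rcpp::export]]
List sample_volume_cpp(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                       int order) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector oob(n);
  const double eps = 1e-9;
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    bool clipped = (x < -eps || y < -eps || z < -eps ||
                    x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps);
    oob[p] = clipped;
    if (clipped) {
      x = std::min(std::max(x, 0.0), (double)(nx - 1));
      y = std::min(std::max(y, 0.0), (double)(ny - 1));
      z = std::min(std::max(z, 0.0), (double)(nz - 1));
    }
    if (order == 1) {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      i0 = clampi(i0, 0, nx - 2 >= 0 ? nx - 2 : 0);
      j0 = clampi(j0, 0, ny - 2 >= 0 ? ny - 2 : 0);
      k0 = clampi(k0, 0, nz - 2 >= 0 ? nz - 2 : 0);
      double fx = x - i0, fy = y - j0, fz = z - k0;
      double acc = 0.0;
      for (int dk = 0; dk < 2; ++dk) {
        double wz = dk ? fz : 1.0 - fz;
        for (int dj = 0; dj < 2; ++dj) {
          double wy = dj ? fy : 1.0 - fy;
          for (int di = 0; di < 2; ++di) {
            double wx = di ? fx : 1.0 - fx;
            int ii = clampi(i0 + di, 0, nx - 1);
            int jj = clampi(j0 + dj, 0, ny - 1);
            int kk = clampi(k0 + dk, 0, nz - 1);
            acc += wx * wy * wz * vol[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          }
        }
      }
      out[p] = acc;
    } else {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      double wx[4], wy[4], wz[4];
      cr_weights(x - i0, wx);
      cr_weights(y - j0, wy);
      cr_weights(z - k0, wz);
      double acc = 0.0;
      for (int dk = 0; dk < 4; ++dk) {
        int kk = clampi(k0 - 1 + dk, 0, nz - 1);
        for (int dj = 0; dj < 4; ++dj) {
          int jj = clampi(j0 - 1 + dj, 0, ny - 1);
          double wzy = wz[dk] * wy[dj];
          for (int di = 0; di < 4; ++di) {
            int ii = clampi(i0 - 1 + di, 0, nx - 1);
            acc += wx[di] * wzy * vol[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          }
        }
      }
      out[p] = acc;
    }
  }
  return List::create(_["values"] = out, _["oob"] = oob);
}

// Separable 1D convolution along one axis with edge replication.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kn = kernel.size();
  const int kr = kn / 2;  // kernel assumed odd length, centred
  NumericVector out(vol.size());
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];
  // iterate over all lines along `axis`
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  for (int k = 0; k < n[b2]; ++k) {
    for (int j = 0; j < n[b1]; ++j) {
      R_xlen_t base = (R_xlen_t)j * stride[b1] + (R_xlen_t)k * stride[b2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int t = 0; t < kn; ++t) {
          int src = i + t - kr;
          src = clampi(src, 0, na - 1);
          acc += kernel[t] * vol[base + (R_xlen_t)src * sa];
        }
        out[base + (R_xlen_t)i * sa] = acc;
      }
    }
  }
  return out;
}

// Strided convolution along one axis: input sampled at fine spacing, output
// only at coarse positions (fine index = offset + stride * j).  Used to
// apply the composite PSF (Gaussian x voxel box) kernel during phantom
// voxelization without materialising a blurred fine grid.
// [[Rcpp::export]]
NumericVector conv_axis_ds_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector kernel, int axis, int stride,
                               int offset) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kn = kernel.size();
  const int kr = kn / 2;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t strd[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const int nout = (na - offset + stride - 1) / stride;
  const R_xlen_t sa = strd[axis];
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  int od[3] = {nx, ny, nz};
  od[axis] = nout;
  const R_xlen_t ostrd[3] = {1, (R_xlen_t)od[0], (R_xlen_t)od[0] * od[1]};
  NumericVector out((R_xlen_t)od[0] * od[1] * od[2]);
  for (int k = 0; k < n[b2]; ++k) {
    for (int j = 0; j < n[b1]; ++j) {
      R_xlen_t base = (R_xlen_t)j * strd[b1] + (R_xlen_t)k * strd[b2];
      R_xlen_t obase = (R_xlen_t)j * ostrd[b1] + (R_xlen_t)k * ostrd[b2];
      for (int o = 0; o < nout; ++o) {
        int centre = offset + o * stride;
        double acc = 0.0;
        for (int t = 0; t < kn; ++t) {
          int src = centre + t - kr;
          src = clampi(src, 0, na - 1);
          acc += kernel[t] * vol[base + (R_xlen_t)src * sa];
        }
        out[obase + (R_xlen_t)o * ostrd[axis]] = acc;
      }
    }
  }
  out.attr("odim") = IntegerVector::create(od[0], od[1], od[2]);
  return out;
}
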