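#include <Rcpp.h>
using namespace Rcpp;

// Separable convolution of a 4D (x, y, z, t) array with per-axis 1D kernels,
// zero-padding outside the grid. Kernels must have odd length.
static void conv_axis(const double *in, double *out,
                      int nx, int ny, int nz, int nt,
                      const double *k, int klen, int axis) {
  int r = (klen - 1) / 2;
  long nxy = (long)nx * ny;
  long nvox = nxy * nz;
  for (int t = 0; t < nt; ++t) {
    const double *src = in + (long)t * nvox;
    double *dst = out + (long)t * nvox;
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        long base = (long)z * nxy + (long)y * nx;
        for (int x = 0; x < nx; ++x) {
          double acc = 0.0;
          for (int o = -r; o <= r; ++o) {
            int xx = x, yy = y, zz = z;
            if (axis == 0) xx += o;
            else if (axis == 1) yy += o;
            else zz += o;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                zz < 0 || zz >= nz) continue;
            acc += k[o + r] * src[(long)zz * nxy + (long)yy * nx + xx];
          }
          dst[base + x] = acc;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_separable_4d")]]
NumericVector conv_separable_4d(NumericVector arr, IntegerVector dims,
                                NumericVector kx, NumericVector ky,
                                NumericVector kz) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nt = dims[3];
  long n = (long)nx * ny * nz * nt;
  if ((long)arr.size() != n) stop("array size does not match dims");
  NumericVector buf(n), out(n);
  conv_axis(arr.begin(), out.begin(), nx, ny, nz, nt, kx.begin(), kx.size(), 0);
  conv_axis(out.begin(), buf.begin(), nx, ny, nz, nt, ky.begin(), ky.size(), 1);
  conv_axis(buf.begin(), out.begin(), nx, ny, nz, nt, kz.begin(), kz.size(), 2);
  out.attr("dim") = dims;
  return out;
}
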