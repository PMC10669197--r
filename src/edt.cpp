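#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform by separable lower-envelope-of-parabolas
// passes (Felzenszwalb & Huttenlocher 2012), generalized to anisotropic
// sample spacing. Distances are to the nearest *in-volume* background voxel
// center, matching the usual ndimage convention; voxels outside the volume
// are not treated as background.

static const double VM_BIG = 1e30;

// one 1-D pass over n samples at positions i*h; f = input squared distances,
// d = output squared distances
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -VM_BIG;
  z[1] = VM_BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s = 0.0;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (k > 0 && s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = VM_BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nt = (size_t)nx * ny * nz;
  std::vector<double> d(nt);
  for (size_t i = 0; i < nt; ++i) d[i] = mask[i] ? VM_BIG : 0.0;

  std::vector<double> line, out;
  // pass along x
  line.resize(nx); out.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) line[x] = d[base + x];
      dt1d(line, out, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) d[base + x] = out[x];
    }
  // pass along y
  line.resize(ny); out.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)x + (size_t)nx * ny * (size_t)z;
      for (int y = 0; y < ny; ++y) line[y] = d[base + (size_t)nx * y];
      dt1d(line, out, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[base + (size_t)nx * y] = out[y];
    }
  // pass along z
  line.resize(nz); out.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)x + (size_t)nx * y;
      for (int z = 0; z < nz; ++z)
        line[z] = d[base + (size_t)nx * ny * (size_t)z];
      dt1d(line, out, nz, spacing[2]);
      for (int z = 0; z < nz; ++z)
        d[base + (size_t)nx * ny * (size_t)z] = out[z];
    }

  NumericVector res(nt);
  for (size_t i = 0; i < nt; ++i)
    res[i] = (d[i] >= VM_BIG) ? R_PosInf : std::sqrt(d[i]);
  return res;
}
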