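#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>

// Exact Euclidean distance transform (squared), separable lower-envelope
// algorithm of Felzenszwalb & Huttenlocher (2012), with per-axis sample
// spacing in mm.  Input: a logical 3-D array marking the feature set;
// output: for every voxel the squared distance (mm^2) from its centre to
// the nearest feature voxel centre (0 inside the feature set).
//
// "Unreachable" costs use a large finite sentinel instead of infinity; for
// equal sentinel heights the envelope intersection degrades to the midpoint
// rule, which keeps the algorithm exact for all reachable voxels.

static const double BIG = 1e30;
// envelope boundary sentinels sit far outside any representable intersection
static const double ZMAX = std::numeric_limits<double>::max();

// 1-D squared distance transform along a line of n samples with spacing h.
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z, double h) {
  const double h2 = h * h;
  int k = 0;
  v[0] = 0;
  z[0] = -ZMAX;
  z[1] = ZMAX;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
               (2.0 * h2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = ZMAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < static_cast<double>(q)) ++k;
    d[q] = h2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared_cpp")]]
Rcpp::NumericVector edt_squared_cpp(Rcpp::LogicalVector mask,
                                    Rcpp::IntegerVector dims,
                                    Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = static_cast<R_xlen_t>(nx) * ny;
  const R_xlen_t n = nxy * nz;
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (mask[i] == TRUE) ? 0.0 : BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* line = &out[0] + k * nxy + static_cast<R_xlen_t>(j) * nx;
      std::copy(line, line + nx, f.begin());
      dt1d(f.data(), d.data(), nx, v, z, spacing[0]);
      std::copy(d.begin(), d.begin() + nx, line);
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double* base = &out[0] + k * nxy + i;
      for (int j = 0; j < ny; ++j) f[j] = base[static_cast<R_xlen_t>(j) * nx];
      dt1d(f.data(), d.data(), ny, v, z, spacing[1]);
      for (int j = 0; j < ny; ++j) base[static_cast<R_xlen_t>(j) * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double* base = &out[0] + static_cast<R_xlen_t>(j) * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = base[k * nxy];
      dt1d(f.data(), d.data(), nz, v, z, spacing[2]);
      for (int k = 0; k < nz; ++k) base[k * nxy] = d[k];
    }
  return out;
}
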