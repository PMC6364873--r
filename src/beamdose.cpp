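#include <Rcpp.h>
#include <cmath>

// Cone-beam dose kernel over the body voxels of one candidate beam.
// dose(v) = output * (SAD / dist)^2 * exp(-mu * (depth - ref_depth)) * P,
// with P = 1 inside the geometric cone (field radius scaled to the voxel
// plane) and an error-function penumbra of width sigma outside. Depth is
// the in-body path length from the ray's entry point (found by bisection
// against the voxelized body, nearest-voxel membership) to the voxel.

static inline bool in_body(const int* bodyv, const int* dim, const double* origin,
                           double h, double px, double py, double pz) {
  const long i = static_cast<long>(std::lround((px - origin[0]) / h));
  const long j = static_cast<long>(std::lround((py - origin[1]) / h));
  const long k = static_cast<long>(std::lround((pz - origin[2]) / h));
  if (i < 0 || i >= dim[0] || j < 0 || j >= dim[1] || k < 0 || k >= dim[2])
    return false;
  return bodyv[i + static_cast<long>(dim[0]) * (j + static_cast<long>(dim[1]) * k)] != 0;
}

// [[Rcpp::export(name = ".beam_entries_cpp")]]
Rcpp::List beam_entries_cpp(Rcpp::LogicalVector body, Rcpp::IntegerVector dim,
                            double spacing, Rcpp::NumericVector origin,
                            Rcpp::NumericMatrix coords,
                            Rcpp::NumericVector src, Rcpp::NumericVector aim,
                            double diameter, double sad, double mu,
                            double sigma, double ref_depth, double output,
                            int n_bisect) {
  const int n = coords.nrow();
  const int* bodyv = body.begin();
  const int* dimv = dim.begin();
  const double* orig = origin.begin();
  double ux = aim[0] - src[0], uy = aim[1] - src[1], uz = aim[2] - src[2];
  const double ulen = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= ulen; uy /= ulen; uz /= ulen;
  const double slope = 0.5 * diameter / sad;
  std::vector<int> idx;
  std::vector<double> val;
  for (int v = 0; v < n; ++v) {
    const double px = coords(v, 0) - src[0];
    const double py = coords(v, 1) - src[1];
    const double pz = coords(v, 2) - src[2];
    const double s_ax = px * ux + py * uy + pz * uz;
    if (s_ax <= 0) continue;
    const double d2 = px * px + py * py + pz * pz;
    const double rho2 = d2 - s_ax * s_ax;
    const double fr = slope * s_ax;
    const double lim = fr + 4.0 * sigma;
    if (rho2 > lim * lim) continue;
    const double rho = rho2 > 0 ? std::sqrt(rho2) : 0.0;
    // entry-point bisection: t=0 at the source (outside), t=1 at the voxel
    double lo = 0.0, hi = 1.0;
    for (int b = 0; b < n_bisect; ++b) {
      const double mid = 0.5 * (lo + hi);
      if (in_body(bodyv, dimv, orig, spacing,
                  src[0] + mid * px, src[1] + mid * py, src[2] + mid * pz))
        hi = mid;
      else
        lo = mid;
    }
    const double len = std::sqrt(d2);
    const double depth = (1.0 - 0.5 * (lo + hi)) * len;
    double pen = 1.0;
    if (rho > fr)
      pen = 2.0 * R::pnorm(-(rho - fr) / sigma, 0.0, 1.0, 1, 0);
    const double dose = output * (sad / len) * (sad / len) *
      std::exp(-mu * (depth - ref_depth)) * pen;
    if (dose > 0) {
      idx.push_back(v + 1);
      val.push_back(dose);
    }
  }
  return Rcpp::List::create(Rcpp::Named("i") = idx, Rcpp::Named("x") = val);
}
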