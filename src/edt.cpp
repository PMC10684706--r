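#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double BIG = 1e20;

// 1-D squared Euclidean distance transform (lower-envelope algorithm) on a
// uniformly spaced line with squared spacing h2. f: input squared distances,
// d: output. v/z: work buffers of length n and n+1.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h2, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (k > 0 && s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    double dq = static_cast<double>(q - p);
    d[q] = h2 * dq * dq + f[p];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel of a 3-D mask, with anisotropic voxel spacing. Voxels of an all-FALSE
// mask get a large sentinel (~1e20).
// [[Rcpp::export]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(n1) * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  double h2 = spacing[0] * spacing[0];
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t base = static_cast<R_xlen_t>(k) * n1 * n2 +
                            static_cast<R_xlen_t>(j) * n1;
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, n1, h2, v, z);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }

  // axis 2 (stride n1)
  h2 = spacing[1] * spacing[1];
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      const R_xlen_t base = static_cast<R_xlen_t>(k) * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) f[j] = out[base + static_cast<R_xlen_t>(j) * n1];
      dt1d(f, d, n2, h2, v, z);
      for (int j = 0; j < n2; ++j) out[base + static_cast<R_xlen_t>(j) * n1] = d[j];
    }

  // axis 3 (stride n1*n2)
  h2 = spacing[2] * spacing[2];
  const R_xlen_t s3 = static_cast<R_xlen_t>(n1) * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const R_xlen_t base = static_cast<R_xlen_t>(j) * n1 + i;
      for (int k = 0; k < n3; ++k) f[k] = out[base + static_cast<R_xlen_t>(k) * s3];
      dt1d(f, d, n3, h2, v, z);
      for (int k = 0; k < n3; ++k) out[base + static_cast<R_xlen_t>(k) * s3] = d[k];
    }

  return out;
}
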