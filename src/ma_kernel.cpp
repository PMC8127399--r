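#include <Rcpp.h>
using namespace Rcpp;

// Accumulate truncated Gaussian focus kernels into a full-grid array.
// Grid must be axis-aligned: voxel (i,j,k) center = origin + i*vx etc.
// combine: 0 = voxel-wise max (nonadditive), 1 = sum (legacy additive).
// [[Rcpp::export(name = ".maAccumulate")]]
NumericVector maAccumulate(IntegerVector dims, NumericVector voxelSizes,
                           NumericVector origin, NumericMatrix foci,
                           double sigma, double radius, double norm,
                           int combine) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector arr(static_cast<R_xlen_t>(nx) * ny * nz);
  const double r2 = radius * radius;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

  for (int f = 0; f < foci.nrow(); ++f) {
    const double fx = foci(f, 0), fy = foci(f, 1), fz = foci(f, 2);
    int ilo = (int)std::floor((fx - radius - origin[0]) / voxelSizes[0]);
    int ihi = (int)std::ceil((fx + radius - origin[0]) / voxelSizes[0]);
    int jlo = (int)std::floor((fy - radius - origin[1]) / voxelSizes[1]);
    int jhi = (int)std::ceil((fy + radius - origin[1]) / voxelSizes[1]);
    int klo = (int)std::floor((fz - radius - origin[2]) / voxelSizes[2]);
    int khi = (int)std::ceil((fz + radius - origin[2]) / voxelSizes[2]);
    if (ilo < 0) ilo = 0; if (ihi > nx - 1) ihi = nx - 1;
    if (jlo < 0) jlo = 0; if (jhi > ny - 1) jhi = ny - 1;
    if (klo < 0) klo = 0; if (khi > nz - 1) khi = nz - 1;
    for (int k = klo; k <= khi; ++k) {
      const double dz = origin[2] + k * voxelSizes[2] - fz;
      const double dz2 = dz * dz;
      if (dz2 > r2) continue;
      for (int j = jlo; j <= jhi; ++j) {
        const double dy = origin[1] + j * voxelSizes[1] - fy;
        const double dyz2 = dy * dy + dz2;
        if (dyz2 > r2) continue;
        R_xlen_t base = (static_cast<R_xlen_t>(k) * ny + j) * nx;
        for (int i = ilo; i <= ihi; ++i) {
          const double dx = origin[0] + i * voxelSizes[0] - fx;
          const double d2 = dx * dx + dyz2;
          if (d2 > r2) continue;
          const double g = norm * std::exp(-d2 * inv2s2);
          if (combine == 0) {
            if (g > arr[base + i]) arr[base + i] = g;
          } else {
            arr[base + i] += g;
          }
        }
      }
    }
  }
  for (R_xlen_t v = 0; v < arr.size(); ++v)
    if (arr[v] >= 1.0) arr[v] = 1.0 - 1e-12;
  return arr;
}

// Complement product over mask voxels: prodCompl * (1 - maFull[mask]).
// maskIdx holds 1-based full-grid indices of mask voxels.
// [[Rcpp::export(name = ".complementProduct")]]
NumericVector complementProduct(NumericVector prodCompl,
                                NumericVector maFull,
                                IntegerVector maskIdx) {
  const R_xlen_t n = maskIdx.size();
  NumericVector out(n);
  for (R_xlen_t v = 0; v < n; ++v)
    out[v] = prodCompl[v] * (1.0 - maFull[maskIdx[v] - 1]);
  return out;
}
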