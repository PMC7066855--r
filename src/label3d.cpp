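#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling of a binary mask stored as a logical
// vector in (z, y, x) column-major order: linear index = iz + nz*(iy + ny*ix).
// connectivity 6 uses face neighbours only; 26 adds edge and corner
// neighbours. Labels are assigned in raster-scan discovery order starting
// at 1; background voxels get 0.
// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3 (nz, ny, nx)");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next_label = 0;

  // precompute neighbour index offsets in (dz, dy, dx)
  std::vector<int> dzs, dys, dxs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manhattan = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manhattan != 1) continue;
        dzs.push_back(dz); dys.push_back(dy); dxs.push_back(dx);
      }
  const int noff = (int)dzs.size();

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.push_back((int)start);
    while (!stack.empty()) {
      int idx = stack.back();
      stack.pop_back();
      int iz = idx % nz;
      int rest = idx / nz;
      int iy = rest % ny;
      int ix = rest / ny;
      for (int k = 0; k < noff; ++k) {
        int jz = iz + dzs[k], jy = iy + dys[k], jx = ix + dxs[k];
        if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx) continue;
        R_xlen_t jdx = jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx);
        if (mask[jdx] && labels[jdx] == 0) {
          labels[jdx] = next_label;
          stack.push_back((int)jdx);
        }
      }
    }
  }
  return labels;
}
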