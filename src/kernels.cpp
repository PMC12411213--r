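#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Trilinear sampling of a 3-D array at fractional 0-based voxel coordinates.
// Coordinates outside the grid return `background`.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix coords, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t k = 0; k < n; ++k) {
    double x = coords(k, 0), y = coords(k, 1), z = coords(k, 2);
    if (!(x >= 0 && y >= 0 && z >= 0 &&
          x <= nx - 1 && y <= ny - 1 && z <= nz - 1)) {
      out[k] = background;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    const R_xlen_t base = x0 * sx + y0 * sy + z0 * sz;
    double c000 = v[base],            c100 = v[base + sx];
    double c010 = v[base + sy],       c110 = v[base + sx + sy];
    double c001 = v[base + sz],       c101 = v[base + sx + sz];
    double c011 = v[base + sy + sz],  c111 = v[base + sx + sy + sz];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[k] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling (for label volumes).
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector vol, IntegerVector dim,
                                 NumericMatrix coords, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t k = 0; k < n; ++k) {
    double x = coords(k, 0), y = coords(k, 1), z = coords(k, 2);
    int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
    if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) {
      out[k] = background;
      continue;
    }
    out[k] = v[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
  }
  return out;
}

// 6-connected components of a 3-D logical mask; labels returned in
// decreasing order of component size (label 1 = largest).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<R_xlen_t> sizes;  // size per provisional label (1-based)
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    R_xlen_t sz_count = 0;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++sz_count;
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      R_xlen_t nb[6];
      int nnb = 0;
      if (x > 0)      nb[nnb++] = cur - sx;
      if (x < nx - 1) nb[nnb++] = cur + sx;
      if (y > 0)      nb[nnb++] = cur - sy;
      if (y < ny - 1) nb[nnb++] = cur + sy;
      if (z > 0)      nb[nnb++] = cur - sz;
      if (z < nz - 1) nb[nnb++] = cur + sz;
      for (int j = 0; j < nnb; ++j) {
        R_xlen_t q = nb[j];
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
    sizes.push_back(sz_count);
  }
  if (next > 1) {
    // rank labels by size, largest first
    std::vector<int> order(next);
    for (int j = 0; j < next; ++j) order[j] = j;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return sizes[a] > sizes[b]; });
    std::vector<int> remap(next + 1, 0);
    for (int r = 0; r < next; ++r) remap[order[r] + 1] = r + 1;
    for (R_xlen_t i = 0; i < ntot; ++i)
      if (lab[i] != 0) lab[i] = remap[lab[i]];
  }
  lab.attr("n_components") = next;
  return lab;
}
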