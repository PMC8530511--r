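#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Mirror an out-of-range index back into [0, n-1] (edge-duplicating reflection).
static inline int reflect_index(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Rank filter over an arbitrary 3D structuring element given as voxel offsets.
// type: 0 = min (erosion), 1 = max (dilation), 2 = median.
// Borders are handled by reflection, so flat regions stay flat at the edges.
// [[Rcpp::export(name = ".rank_filter3d")]]
NumericVector rank_filter3d(NumericVector x, IntegerVector dim,
                            IntegerMatrix offsets, int type) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int k = offsets.nrow();
  NumericVector out(x.size());
  std::vector<double> buf(k);

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int xx = 0; xx < nx; ++xx) {
        if (type == 0 || type == 1) {
          double acc = (type == 0) ? R_PosInf : R_NegInf;
          for (int o = 0; o < k; ++o) {
            int ix = reflect_index(xx + offsets(o, 0), nx);
            int iy = reflect_index(y + offsets(o, 1), ny);
            int iz = reflect_index(z + offsets(o, 2), nz);
            double v = x[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
            if (type == 0) { if (v < acc) acc = v; }
            else           { if (v > acc) acc = v; }
          }
          out[xx + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = acc;
        } else {
          for (int o = 0; o < k; ++o) {
            int ix = reflect_index(xx + offsets(o, 0), nx);
            int iy = reflect_index(y + offsets(o, 1), ny);
            int iz = reflect_index(z + offsets(o, 2), nz);
            buf[o] = x[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
          }
          // median with lower-middle convention for even k matches stats::median
          // only for odd k; structuring elements here always have odd cardinality
          // ... except user-supplied ones, so average the two middles when even.
          std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
          double med = buf[k / 2];
          if (k % 2 == 0) {
            std::nth_element(buf.begin(), buf.begin() + k / 2 - 1,
                             buf.begin() + k / 2);
            med = 0.5 * (med + buf[k / 2 - 1]);
          }
          out[xx + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = med;
        }
      }
    }
  }
  return out;
}

// Separable 1D convolution along one axis (0 = x, 1 = y, 2 = z), reflective
// borders. kernel has odd length and is applied centred.
// [[Rcpp::export(name = ".conv_axis3d")]]
NumericVector conv_axis3d(NumericVector x, IntegerVector dim,
                          NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int k = kernel.size();
  const int r = (k - 1) / 2;
  NumericVector out(x.size());

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int xx = 0; xx < nx; ++xx) {
        double acc = 0.0;
        for (int o = -r; o <= r; ++o) {
          int ix = xx, iy = y, iz = z;
          if (axis == 0) ix = reflect_index(xx + o, nx);
          else if (axis == 1) iy = reflect_index(y + o, ny);
          else iz = reflect_index(z + o, nz);
          acc += kernel[o + r] * x[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        }
        out[xx + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = acc;
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary 3D mask, 26-connectivity,
// iterative depth-first flood fill. Returns integer labels (0 = background).
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      int rem = (int)(idx - (R_xlen_t)z * nx * ny);
      int y = rem / nx;
      int x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int ax = x + dx, ay = y + dy, az = z + dz;
            if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
              continue;
            R_xlen_t aidx = ax + (R_xlen_t)nx * (ay + (R_xlen_t)ny * az);
            if (mask[aidx] && labels[aidx] == 0) {
              labels[aidx] = next_label;
              stack.push_back(aidx);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
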