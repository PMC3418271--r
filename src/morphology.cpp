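#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Voxel arrays are stored dim = c(nz, ny, nx), i.e. column-major index
// idx = z + nz*(y + ny*x) with 0-based z, y, x.  All kernels below keep
// that convention; per-slice ("2D") operations act on the (y, x) plane
// of each z slice.

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

// Per-slice flood fill of air from the slice border, 8-connectivity.
// Returns the external-air mask: air components touching the slice edge.
// [[Rcpp::export]]
LogicalVector cpp_border_air_2d(LogicalVector air, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out(air.size());
  std::vector<std::pair<int,int> > stack;
  std::vector<char> seen((size_t)ny * nx);
  for (int z = 0; z < nz; ++z) {
    std::fill(seen.begin(), seen.end(), 0);
    stack.clear();
    // seed from every air pixel on the slice border
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        if (y != 0 && y != ny - 1 && x != 0 && x != nx - 1) continue;
        if (air[vidx(z, y, x, nz, ny)]) {
          size_t s = (size_t)y + (size_t)ny * x;
          if (!seen[s]) { seen[s] = 1; stack.push_back(std::make_pair(y, x)); }
        }
      }
    }
    while (!stack.empty()) {
      int y = stack.back().first, x = stack.back().second;
      stack.pop_back();
      out[vidx(z, y, x, nz, ny)] = true;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          if (dy == 0 && dx == 0) continue;
          int yy = y + dy, xx = x + dx;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          size_t s = (size_t)yy + (size_t)ny * xx;
          if (!seen[s] && air[vidx(z, yy, xx, nz, ny)]) {
            seen[s] = 1;
            stack.push_back(std::make_pair(yy, xx));
          }
        }
      }
    }
  }
  return out;
}

// Per-slice binary erosion by a square (Chebyshev) structuring element of
// radius r (side 2r+1), separable as a running minimum along y then x.
// Pixels whose window leaves the slice are eroded (background border).
// [[Rcpp::export]]
LogicalVector cpp_erode2d_square(LogicalVector mask, IntegerVector dims, int r) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  if (r == 0) return clone(mask);
  LogicalVector tmp(mask.size()), out(mask.size());
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {     // pass 1: min over y-window
      for (int y = 0; y < ny; ++y) {
        bool keep = (y - r >= 0) && (y + r <= ny - 1);
        if (keep) {
          for (int dy = -r; dy <= r && keep; ++dy)
            if (!mask[vidx(z, y + dy, x, nz, ny)]) keep = false;
        }
        tmp[vidx(z, y, x, nz, ny)] = keep;
      }
    }
    for (int y = 0; y < ny; ++y) {     // pass 2: min over x-window
      for (int x = 0; x < nx; ++x) {
        bool keep = (x - r >= 0) && (x + r <= nx - 1);
        if (keep) {
          for (int dx = -r; dx <= r && keep; ++dx)
            if (!tmp[vidx(z, y, x + dx, nz, ny)]) keep = false;
        }
        out[vidx(z, y, x, nz, ny)] = keep;
      }
    }
  }
  return out;
}

// 3D connected-component labeling, 26-connectivity.  Components are
// numbered in lexicographic (z, y, x) discovery order, so the seed voxel
// of label k is the lexicographically smallest voxel of component k and
// label ids themselves order the tie-break.  Returns labels (0 =
// background) and component sizes.
// [[Rcpp::export]]
List cpp_label3d_26(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector labels(mask.size());
  std::vector<double> sizes;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i0 = vidx(z, y, x, nz, ny);
        if (!mask[i0] || labels[i0]) continue;
        ++next;
        double sz = 0;
        labels[i0] = next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          R_xlen_t i = stack.back();
          stack.pop_back();
          ++sz;
          int cz = (int)(i % nz);
          int cy = (int)((i / nz) % ny);
          int cx = (int)(i / ((R_xlen_t)nz * ny));
          for (int dz = -1; dz <= 1; ++dz) {
            for (int dy = -1; dy <= 1; ++dy) {
              for (int dx = -1; dx <= 1; ++dx) {
                if (dz == 0 && dy == 0 && dx == 0) continue;
                int zz = cz + dz, yy = cy + dy, xx = cx + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                    xx < 0 || xx >= nx) continue;
                R_xlen_t j = vidx(zz, yy, xx, nz, ny);
                if (mask[j] && !labels[j]) {
                  labels[j] = next;
                  stack.push_back(j);
                }
              }
            }
          }
        }
        sizes.push_back(sz);
      }
    }
  }
  return List::create(_["labels"] = labels,
                      _["sizes"] = NumericVector(sizes.begin(), sizes.end()));
}
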