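#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3D binary morphology with an arbitrary offset set (structuring element).
// Masks are logical arrays; offsets are a k x 3 integer matrix of voxel
// displacements.  Out-of-bounds neighbours count as background: erosion
// shrinks at the volume faces, dilation never writes outside.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
LogicalVector cpp_binary_erode(LogicalVector mask, IntegerVector dim,
                               IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int noff = offsets.nrow();
  LogicalVector out(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int p = idx3(i, j, k, nx, ny);
        if (!mask[p]) { out[p] = false; continue; }
        bool keep = true;
        for (int o = 0; o < noff; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz ||
              !mask[idx3(ii, jj, kk, nx, ny)]) { keep = false; break; }
        }
        out[p] = keep;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dim,
                                IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int noff = offsets.nrow();
  LogicalVector out(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int p = idx3(i, j, k, nx, ny);
        if (!mask[p]) continue;
        for (int o = 0; o < noff; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            out[idx3(ii, jj, kk, nx, ny)] = true;
        }
      }
  return out;
}

// Connected-component labelling, 6- or 26-connectivity.  Labels are
// 1-based in first-encounter order (scan order x fastest); background 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector labels(mask.size(), 0);
  std::vector<std::array<int, 3>> nb;
  if (connectivity == 6) {
    nb = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) nb.push_back({{dx, dy, dz}});
  }
  int next = 0;
  std::queue<std::array<int, 3>> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int p = idx3(i, j, k, nx, ny);
        if (!mask[p] || labels[p]) continue;
        labels[p] = ++next;
        q.push({{i, j, k}});
        while (!q.empty()) {
          std::array<int, 3> v = q.front(); q.pop();
          for (size_t o = 0; o < nb.size(); ++o) {
            int ii = v[0] + nb[o][0], jj = v[1] + nb[o][1], kk = v[2] + nb[o][2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int pp = idx3(ii, jj, kk, nx, ny);
            if (mask[pp] && !labels[pp]) {
              labels[pp] = next;
              q.push({{ii, jj, kk}});
            }
          }
        }
      }
  return labels;
}

// Fill 2D holes slice by slice along the third axis: background pixels not
// 4-connected to the slice border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_2d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(mask);
  std::vector<char> outside(nx * ny);
  std::queue<std::pair<int, int>> q;
  for (int k = 0; k < nz; ++k) {
    std::fill(outside.begin(), outside.end(), 0);
    int base = nx * ny * k;
    // seed from border background pixels
    for (int i = 0; i < nx; ++i)
      for (int j : {0, ny - 1}) {
        int p = i + nx * j;
        if (!mask[base + p] && !outside[p]) { outside[p] = 1; q.push({i, j}); }
      }
    for (int j = 0; j < ny; ++j)
      for (int i : {0, nx - 1}) {
        int p = i + nx * j;
        if (!mask[base + p] && !outside[p]) { outside[p] = 1; q.push({i, j}); }
      }
    const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
    while (!q.empty()) {
      std::pair<int, int> v = q.front(); q.pop();
      for (int o = 0; o < 4; ++o) {
        int ii = v.first + dx[o], jj = v.second + dy[o];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        int p = ii + nx * jj;
        if (!mask[base + p] && !outside[p]) { outside[p] = 1; q.push({ii, jj}); }
      }
    }
    for (int p = 0; p < nx * ny; ++p)
      if (!mask[base + p] && !outside[p]) out[base + p] = true;
  }
  return out;
}
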