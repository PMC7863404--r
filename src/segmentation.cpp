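// 3D segmentation primitives for confocal stacks.
// Arrays are column-major with dims (nx, ny, nz), matching R.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Connected-component labelling of a binary mask, 26-connectivity.
// Returns an integer array of labels (0 = background), labelled in
// raster-scan order so labels are deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;

  int next_label = 0;
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int i = idx3(x, y, z, nx, ny);
        if (!mask[i] || labels[i] != 0) continue;
        labels[i] = ++next_label;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          const int cur = stack.back();
          stack.pop_back();
          const int cz = cur / (nx * ny);
          const int cy = (cur / nx) % ny;
          const int cx = cur % nx;
          for (int dz = -1; dz <= 1; ++dz) {
            for (int dy = -1; dy <= 1; ++dy) {
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int qx = cx + dx, qy = cy + dy, qz = cz + dz;
                if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                    qz < 0 || qz >= nz) continue;
                const int q = idx3(qx, qy, qz, nx, ny);
                if (mask[q] && labels[q] == 0) {
                  labels[q] = next_label;
                  stack.push_back(q);
                }
              }
            }
          }
        }
      }
    }
  }
  return labels;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher parabolas),
// with physical sample spacing `step`.
static void dt1d(std::vector<double>& f, double step) {
  const int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    const double xq = q * step;
    double s;
    while (true) {
      const double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s > zz[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    zz[k] = s;
    zz[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * step;
    while (zz[k + 1] < xq) ++k;
    const double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
  f.swap(d);
}

// Euclidean distance (um) from each foreground voxel to the nearest
// background voxel, with anisotropic voxel spacing. Exact separable EDT.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, NumericVector voxel_size) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  if (voxel_size.size() != 3) stop("voxel_size must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;

  NumericVector out(mask.size());
  out.attr("dim") = dims;
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> line;
  // pass along x
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) line[x] = out[idx3(x, y, z, nx, ny)];
      dt1d(line, voxel_size[0]);
      for (int x = 0; x < nx; ++x) out[idx3(x, y, z, nx, ny)] = line[x];
    }
  // pass along y
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = out[idx3(x, y, z, nx, ny)];
      dt1d(line, voxel_size[1]);
      for (int y = 0; y < ny; ++y) out[idx3(x, y, z, nx, ny)] = line[y];
    }
  // pass along z
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) line[z] = out[idx3(x, y, z, nx, ny)];
      dt1d(line, voxel_size[2]);
      for (int z = 0; z < nz; ++z) out[idx3(x, y, z, nx, ny)] = line[z];
    }

  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// Regional maxima of `values` restricted to `mask`, 26-connectivity:
// voxels not strictly below any neighbour, with plateaus merged into a
// single marker per connected plateau. Maxima below min_value are dropped.
// Returns integer marker labels.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector values, LogicalVector mask,
                                  double min_value) {
  IntegerVector dims = values.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector is_max(values.size());
  is_max.attr("dim") = dims;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = idx3(x, y, z, nx, ny);
        if (!mask[i] || values[i] < min_value) { is_max[i] = false; continue; }
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dx = -1; dx <= 1 && ok; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int qx = x + dx, qy = y + dy, qz = z + dz;
              if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                  qz < 0 || qz >= nz) continue;
              if (values[idx3(qx, qy, qz, nx, ny)] > values[i]) ok = false;
            }
        is_max[i] = ok;
      }
  return cpp_label_components(is_max);
}

struct FloodNode {
  double priority;
  long order;
  int index;
  int label;
};
struct FloodCompare {
  bool operator()(const FloodNode& a, const FloodNode& b) const {
    if (a.priority != b.priority) return a.priority < b.priority;
    return a.order > b.order;  // FIFO among equal priorities
  }
};

// Marker-based watershed by priority flooding: regions grow outward from
// markers in order of decreasing `priority` (e.g. the distance transform),
// so touching objects are split along priority ridges. 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            LogicalVector mask) {
  IntegerVector dims = priority.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector labels(priority.size(), 0);
  labels.attr("dim") = dims;

  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCompare> pq;
  long order = 0;
  for (R_xlen_t i = 0; i < markers.size(); ++i)
    if (markers[i] > 0 && mask[i])
      pq.push({priority[i], order++, (int)i, markers[i]});

  const int dx6[6] = {-1, 1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, -1, 1, 0, 0};
  const int dz6[6] = {0, 0, 0, 0, -1, 1};

  while (!pq.empty()) {
    FloodNode node = pq.top();
    pq.pop();
    if (labels[node.index] != 0) continue;
    labels[node.index] = node.label;
    const int cz = node.index / (nx * ny);
    const int cy = (node.index / nx) % ny;
    const int cx = node.index % nx;
    for (int k = 0; k < 6; ++k) {
      const int qx = cx + dx6[k], qy = cy + dy6[k], qz = cz + dz6[k];
      if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
        continue;
      const int q = idx3(qx, qy, qz, nx, ny);
      if (mask[q] && labels[q] == 0)
        pq.push({priority[q], order++, q, node.label});
    }
  }
  return labels;
}
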