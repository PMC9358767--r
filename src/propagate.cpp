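#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source best-first contour propagation on a masked 3D grid.
//
// Each region starts at its seed voxel. A single global max-priority queue
// holds frontier entries (priority, candidate label, voxel). In "plain" mode
// the priority is the voxel intensity; in "distance_modified" mode it is
// intensity / max(distance, floor) where the distance is the 3D Euclidean
// world distance from the voxel center to the landmark of the candidate
// region ("candidate") or to the nearest landmark ("nearest"), and the floor
// is the smallest voxel spacing. Ties are broken by lower candidate label id,
// then lower linear (lexicographic) voxel index, so the output is fully
// deterministic. Growth is 6-connected and confined to the mask.

struct Entry {
  double pri;
  int label;
  int idx;
};

struct EntryLess {
  // max-heap on priority; on ties prefer LOWER label, then LOWER index
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.pri != b.pri) return a.pri < b.pri;
    if (a.label != b.label) return a.label > b.label;
    return a.idx > b.idx;
  }
};

// [[Rcpp::export(name = ".propagate_cpp")]]
IntegerVector propagate_cpp(NumericVector intensity, IntegerVector mask,
                            IntegerVector dims, NumericVector spacing,
                            NumericVector origin, IntegerVector seed_idx,
                            IntegerVector seed_label, NumericMatrix seed_pos,
                            int mode, int dist_ref) {
  // mode: 0 = plain, 1 = distance modified
  // dist_ref: 0 = candidate region's landmark, 1 = nearest landmark
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int ns = seed_idx.size();
  IntegerVector labels(n, 0);

  const double dfloor = std::min(spacing[0], std::min(spacing[1], spacing[2]));

  std::vector<double> sx(ns), sy(ns), sz(ns); // seed world positions by label slot
  std::vector<int> slot_of_label; // label id -> slot
  int max_label = 0;
  for (int s = 0; s < ns; ++s) max_label = std::max(max_label, seed_label[s]);
  slot_of_label.assign(max_label + 1, -1);
  for (int s = 0; s < ns; ++s) {
    slot_of_label[seed_label[s]] = s;
    sx[s] = seed_pos(s, 0); sy[s] = seed_pos(s, 1); sz[s] = seed_pos(s, 2);
  }

  auto world = [&](int idx, double* w) {
    int i = idx % nx, j = (idx / nx) % ny, k = idx / (nx * ny);
    w[0] = origin[0] + (i + 0.5) * spacing[0];
    w[1] = origin[1] + (j + 0.5) * spacing[1];
    w[2] = origin[2] + (k + 0.5) * spacing[2];
  };

  auto priority = [&](int idx, int label) -> double {
    double I = intensity[idx];
    if (mode == 0) return I;
    double w[3];
    world(idx, w);
    double d;
    if (dist_ref == 0) {
      int s = slot_of_label[label];
      double dx = w[0] - sx[s], dy = w[1] - sy[s], dz = w[2] - sz[s];
      d = std::sqrt(dx * dx + dy * dy + dz * dz);
    } else {
      d = R_PosInf;
      for (int s = 0; s < ns; ++s) {
        double dx = w[0] - sx[s], dy = w[1] - sy[s], dz = w[2] - sz[s];
        double dd = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dd < d) d = dd;
      }
    }
    return I / std::max(d, dfloor);
  };

  std::priority_queue<Entry, std::vector<Entry>, EntryLess> q;

  const int delta_i[6] = {-1, 1, 0, 0, 0, 0};
  const int delta_j[6] = {0, 0, -1, 1, 0, 0};
  const int delta_k[6] = {0, 0, 0, 0, -1, 1};

  auto push_neighbors = [&](int idx, int label) {
    int i = idx % nx, j = (idx / nx) % ny, k = idx / (nx * ny);
    for (int t = 0; t < 6; ++t) {
      int ii = i + delta_i[t], jj = j + delta_j[t], kk = k + delta_k[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      int nidx = ii + nx * (jj + (R_xlen_t)ny * kk);
      if (mask[nidx] && labels[nidx] == 0)
        q.push({priority(nidx, label), label, nidx});
    }
  };

  for (int s = 0; s < ns; ++s) {
    int idx = seed_idx[s];
    if (!mask[idx]) stop("seed for label %d lies outside the mask", seed_label[s]);
    labels[idx] = seed_label[s];
  }
  for (int s = 0; s < ns; ++s) push_neighbors(seed_idx[s], seed_label[s]);

  while (!q.empty()) {
    Entry e = q.top();
    q.pop();
    if (labels[e.idx] != 0) continue;
    labels[e.idx] = e.label;
    push_neighbors(e.idx, e.label);
  }

  labels.attr("dim") = dims;
  return labels;
}
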