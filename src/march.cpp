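#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Marching tetrahedra isosurface extraction.
//
// Each grid cell spanned by 8 neighboring voxel centers is split into six
// tetrahedra sharing the main diagonal; the iso-level crossing inside every
// tetrahedron is triangulated with vertices placed by linear interpolation
// along crossing edges. Shared vertices are deduplicated via the (corner,
// corner) edge key, so the output mesh is watertight wherever the field is.
// Triangles are oriented so normals point away from the >= iso region
// (outward for a high-intensity foreground).

struct VKey {
  int64_t a, b;
  bool operator==(const VKey& o) const { return a == o.a && b == o.b; }
};
struct VKeyHash {
  size_t operator()(const VKey& k) const {
    return std::hash<int64_t>()(k.a * 2654435761LL + k.b);
  }
};

// [[Rcpp::export(name = ".march_tetra_cpp")]]
List march_tetra_cpp(NumericVector field, IntegerVector dims,
                     NumericVector spacing, NumericVector origin, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto fid = [&](int i, int j, int k) -> int64_t {
    return i + (int64_t)nx * (j + (int64_t)ny * k);
  };

  static const int tets[6][4] = {
    {0, 1, 5, 7}, {0, 5, 4, 7}, {0, 4, 6, 7},
    {0, 6, 2, 7}, {0, 2, 3, 7}, {0, 3, 1, 7}};

  std::vector<double> vx, vy, vz;
  std::vector<int> tri; // 0-based vertex ids, 3 per triangle
  std::unordered_map<VKey, int, VKeyHash> vert_of_edge;

  double cpos[8][3];
  double cval[8];
  int64_t cgid[8];

  auto edge_vertex = [&](int a, int b) -> int {
    VKey key{std::min(cgid[a], cgid[b]), std::max(cgid[a], cgid[b])};
    auto it = vert_of_edge.find(key);
    if (it != vert_of_edge.end()) return it->second;
    double f0 = cval[a], f1 = cval[b];
    double t = (f1 == f0) ? 0.5 : (iso - f0) / (f1 - f0);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    int id = (int)vx.size();
    vx.push_back(cpos[a][0] + t * (cpos[b][0] - cpos[a][0]));
    vy.push_back(cpos[a][1] + t * (cpos[b][1] - cpos[a][1]));
    vz.push_back(cpos[a][2] + t * (cpos[b][2] - cpos[a][2]));
    vert_of_edge[key] = id;
    return id;
  };

  auto emit = [&](int p0, int p1, int p2, const double* inside_mean) {
    // orient so the normal points away from the inside (>= iso) corners
    double ax = vx[p1] - vx[p0], ay = vy[p1] - vy[p0], az = vz[p1] - vz[p0];
    double bx = vx[p2] - vx[p0], by = vy[p2] - vy[p0], bz = vz[p2] - vz[p0];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz,
           nzv = ax * by - ay * bx;
    double cx = (vx[p0] + vx[p1] + vx[p2]) / 3.0 - inside_mean[0];
    double cy = (vy[p0] + vy[p1] + vy[p2]) / 3.0 - inside_mean[1];
    double cz = (vz[p0] + vz[p1] + vz[p2]) / 3.0 - inside_mean[2];
    if (nxv * cx + nyv * cy + nzv * cz < 0) std::swap(p1, p2);
    tri.push_back(p0); tri.push_back(p1); tri.push_back(p2);
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          cgid[c] = fid(ci, cj, ck);
          cval[c] = field[cgid[c]];
          cpos[c][0] = origin[0] + (ci + 0.5) * spacing[0];
          cpos[c][1] = origin[1] + (cj + 0.5) * spacing[1];
          cpos[c][2] = origin[2] + (ck + 0.5) * spacing[2];
          (cval[c] >= iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], out[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c)
            (cval[vi[c]] >= iso ? in[ni++] : out[no++]) = vi[c];
          if (ni == 0 || ni == 4) continue;
          double im[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int d = 0; d < 3; ++d) im[d] += cpos[in[c]][d] / ni;
          if (ni == 1) {
            int p0 = edge_vertex(in[0], out[0]);
            int p1 = edge_vertex(in[0], out[1]);
            int p2 = edge_vertex(in[0], out[2]);
            emit(p0, p1, p2, im);
          } else if (ni == 3) {
            int p0 = edge_vertex(out[0], in[0]);
            int p1 = edge_vertex(out[0], in[1]);
            int p2 = edge_vertex(out[0], in[2]);
            emit(p0, p1, p2, im);
          } else { // 2 in, 2 out -> quad
            int q0 = edge_vertex(in[0], out[0]);
            int q1 = edge_vertex(in[0], out[1]);
            int q2 = edge_vertex(in[1], out[1]);
            int q3 = edge_vertex(in[1], out[0]);
            emit(q0, q1, q2, im);
            emit(q0, q2, q3, im);
          }
        }
      }

  int nvert = (int)vx.size();
  NumericMatrix V(nvert, 3);
  for (int v = 0; v < nvert; ++v) {
    V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v];
  }
  int nf = (int)tri.size() / 3;
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = tri[3 * f] + 1;
    F(f, 1) = tri[3 * f + 1] + 1;
    F(f, 2) = tri[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// For each query point, the label of the nearest nonzero voxel, searched in
// expanding cubic rings around the voxel containing the point.
// [[Rcpp::export(name = ".nearest_label_cpp")]]
IntegerVector nearest_label_cpp(NumericMatrix pts, IntegerVector labels,
                                IntegerVector dims, NumericVector spacing,
                                NumericVector origin, int max_ring) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  IntegerVector out(n, 0);
  for (int q = 0; q < n; ++q) {
    int i0 = (int)std::floor((pts(q, 0) - origin[0]) / spacing[0]);
    int j0 = (int)std::floor((pts(q, 1) - origin[1]) / spacing[1]);
    int k0 = (int)std::floor((pts(q, 2) - origin[2]) / spacing[2]);
    i0 = std::max(0, std::min(nx - 1, i0));
    j0 = std::max(0, std::min(ny - 1, j0));
    k0 = std::max(0, std::min(nz - 1, k0));
    int best_lab = 0;
    double best_d = R_PosInf;
    for (int ring = 0; ring <= max_ring; ++ring) {
      if (best_lab != 0 && ring > 1 &&
          (double)(ring - 1) * std::min(spacing[0],
            std::min(spacing[1], spacing[2])) > std::sqrt(best_d))
        break;
      for (int dk = -ring; dk <= ring; ++dk)
        for (int dj = -ring; dj <= ring; ++dj)
          for (int di = -ring; di <= ring; ++di) {
            if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk)))
                != ring)
              continue;
            int i = i0 + di, j = j0 + dj, k = k0 + dk;
            if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
              continue;
            int lab = labels[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
            if (lab == 0) continue;
            double dx = origin[0] + (i + 0.5) * spacing[0] - pts(q, 0);
            double dy = origin[1] + (j + 0.5) * spacing[1] - pts(q, 1);
            double dz = origin[2] + (k + 0.5) * spacing[2] - pts(q, 2);
            double d = dx * dx + dy * dy + dz * dz;
            if (d < best_d) { best_d = d; best_lab = lab; }
          }
    }
    out[q] = best_lab;
  }
  return out;
}
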