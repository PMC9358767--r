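#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Superellipsoid implicit "radius": f(x) = (sum_i |x_i / r_i|^p)^(1/p).
// f < 1 inside, f = 1 on the surface, f > 1 outside.
static inline double se_f(double x, double y, double z, const double* r,
                          double p) {
  double s = std::pow(std::fabs(x / r[0]), p) +
             std::pow(std::fabs(y / r[1]), p) +
             std::pow(std::fabs(z / r[2]), p);
  return std::pow(s, 1.0 / p);
}

// Binary shell support: voxel centers between the outer superellipsoid
// (radii r) and the inner offset superellipsoid (radii r - thickness).
// [[Rcpp::export(name = ".shell_support_cpp")]]
IntegerVector shell_support_cpp(IntegerVector dims, NumericVector spacing,
                                NumericVector origin, NumericVector center,
                                NumericVector radii, double p,
                                double thickness) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz, 0);
  double rin[3], rout[3];
  for (int c = 0; c < 3; ++c) {
    rout[c] = radii[c];
    rin[c] = std::max(radii[c] - thickness, 1e-9);
  }
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + (k + 0.5) * spacing[2] - center[2];
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + (j + 0.5) * spacing[1] - center[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = origin[0] + (i + 0.5) * spacing[0] - center[0];
        if (se_f(x, y, z, rout, p) <= 1.0 && se_f(x, y, z, rin, p) >= 1.0)
          out[idx] = 1;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Nearest-site labeling: for each listed voxel (1-based linear index) return
// the label of the nearest site (world coordinates, squared Euclidean).
// [[Rcpp::export(name = ".nearest_site_cpp")]]
IntegerVector nearest_site_cpp(IntegerVector lin_idx, IntegerVector dims,
                               NumericVector spacing, NumericVector origin,
                               NumericMatrix sites, IntegerVector site_labels) {
  const int nx = dims[0], ny = dims[1];
  const int ns = sites.nrow();
  const R_xlen_t n = lin_idx.size();
  IntegerVector out(n);
  std::vector<double> sx(ns), sy(ns), sz(ns);
  for (int s = 0; s < ns; ++s) {
    sx[s] = sites(s, 0); sy[s] = sites(s, 1); sz[s] = sites(s, 2);
  }
  for (R_xlen_t v = 0; v < n; ++v) {
    R_xlen_t idx = (R_xlen_t)lin_idx[v] - 1;
    int i = idx % nx, j = (idx / nx) % ny, k = idx / ((R_xlen_t)nx * ny);
    double x = origin[0] + (i + 0.5) * spacing[0];
    double y = origin[1] + (j + 0.5) * spacing[1];
    double z = origin[2] + (k + 0.5) * spacing[2];
    double best = R_PosInf;
    int arg = 0;
    for (int s = 0; s < ns; ++s) {
      double dx = x - sx[s], dy = y - sy[s], dz = z - sz[s];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; arg = s; }
    }
    out[v] = site_labels[arg];
  }
  return out;
}

// Count 6-adjacent voxel pairs carrying two different nonzero labels.
// Returns a 3-column matrix (label a, label b, face count), a < b.
// [[Rcpp::export(name = ".label_contacts_cpp")]]
IntegerMatrix label_contacts_cpp(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::map<std::pair<int, int>, int> cnt;
  auto at = [&](int i, int j, int k) -> int {
    return labels[i + nx * (j + (R_xlen_t)ny * k)];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = at(i, j, k);
        if (a == 0) continue;
        if (i + 1 < nx) {
          int b = at(i + 1, j, k);
          if (b != 0 && b != a)
            cnt[{std::min(a, b), std::max(a, b)}]++;
        }
        if (j + 1 < ny) {
          int b = at(i, j + 1, k);
          if (b != 0 && b != a)
            cnt[{std::min(a, b), std::max(a, b)}]++;
        }
        if (k + 1 < nz) {
          int b = at(i, j, k + 1);
          if (b != 0 && b != a)
            cnt[{std::min(a, b), std::max(a, b)}]++;
        }
      }
  IntegerMatrix out(cnt.size(), 3);
  int r = 0;
  for (auto& kv : cnt) {
    out(r, 0) = kv.first.first;
    out(r, 1) = kv.first.second;
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}
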