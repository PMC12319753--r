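#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Threshold-free cluster enhancement of a 3D map.
// score(v) = sum over thresholds h of  e(h, v)^E * h^H * dh,
// where e(h, v) is the voxel count of the suprathreshold (map >= h)
// connected component containing v. Negative map values never contribute.
// dh <= 0 selects max(map) / n_steps.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector map, IntegerVector dims,
                       LogicalVector mask, double H, double E, double dh,
                       int connectivity, int n_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  NumericVector score(V);

  // neighbour offsets for the requested connectivity
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back(dx + dy * nx + dz * nx * ny);
      }

  double maxval = 0.0;
  std::vector<int> in_mask;
  in_mask.reserve(V);
  for (int v = 0; v < V; ++v) {
    if (!mask[v]) continue;
    in_mask.push_back(v);
    double x = map[v];
    if (R_finite(x) && x > maxval) maxval = x;
  }
  if (maxval <= 0.0) return score;
  if (dh <= 0.0) dh = maxval / n_steps;

  std::vector<int> parent(V, -1), xs(V), ys(V), zs(V);
  for (int z = 0, v = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++v) { xs[v] = x; ys[v] = y; zs[v] = z; }

  std::vector<int> active;
  active.reserve(in_mask.size());
  std::vector<int> csize(V);

  // index the thresholds so the top step is included whenever max(map) is
  // an (approximate) multiple of dh, immune to accumulation error
  const int n_thr = (int)std::floor(maxval / dh + 1e-9);
  const double tol = 1e-9 * dh;
  for (int step = 1; step <= n_thr; ++step) {
    const double h = step * dh;
    active.clear();
    for (size_t i = 0; i < in_mask.size(); ++i) {
      int v = in_mask[i];
      double x = map[v];
      if (R_finite(x) && x >= h - tol) {
        active.push_back(v);
        parent[v] = v;
      } else {
        parent[v] = -1;
      }
    }
    if (active.empty()) break;
    for (size_t i = 0; i < active.size(); ++i) {
      int v = active[i];
      for (size_t o = 0; o < offs.size(); ++o) {
        int u = v + offs[o];
        if (u < 0 || u >= V || parent[u] < 0) continue;
        // guard against wrap-around across volume faces
        if (std::abs(xs[u] - xs[v]) > 1 || std::abs(ys[u] - ys[v]) > 1 ||
            std::abs(zs[u] - zs[v]) > 1) continue;
        int ra = find_root(parent, v), rb = find_root(parent, u);
        if (ra != rb) parent[rb] = ra;
      }
    }
    for (size_t i = 0; i < active.size(); ++i)
      csize[find_root(parent, active[i])] = 0;
    for (size_t i = 0; i < active.size(); ++i)
      ++csize[find_root(parent, active[i])];
    const double hterm = std::pow(h, H) * dh;
    for (size_t i = 0; i < active.size(); ++i) {
      int v = active[i];
      score[v] += std::pow((double)csize[find_root(parent, v)], E) * hterm;
    }
  }
  return score;
}
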