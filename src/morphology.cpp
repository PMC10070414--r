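// Voxel morphology kernels: connected-component labeling (6-connectivity),
// exact Euclidean distance transform (optionally periodic), local-thickness
// sphere painting, and marker-based watershed on a priority field.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline int64_t vidx(int x, int y, int z, int nx, int ny) {
  return (int64_t)x + (int64_t)nx * ((int64_t)y + (int64_t)ny * z);
}

// Label connected components of `mask` under face (6-) connectivity,
// non-periodic: fragments touching opposite box faces stay distinct.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int64_t> stack;
  int cur = 0;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      int64_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((int64_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int64_t w = vidx(xx, yy, zz, nx, ny);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

static const double EDT_INF = 1e18;

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher) over
// parabolas rooted at positions `pos` with heights `f`; infinite heights are
// skipped. Evaluated at query positions `q`.
static void edt_1d(const std::vector<double>& f, const std::vector<double>& pos,
                   int m, const std::vector<double>& q, std::vector<double>& out) {
  std::vector<int> keep;
  keep.reserve(m);
  for (int i = 0; i < m; ++i) if (f[i] < EDT_INF) keep.push_back(i);
  if (keep.empty()) {
    std::fill(out.begin(), out.end(), EDT_INF);
    return;
  }
  const int mm = (int)keep.size();
  std::vector<int> v(mm);
  std::vector<double> z(mm + 1);
  int k = 0;
  v[0] = keep[0]; z[0] = -EDT_INF; z[1] = EDT_INF;
  for (int ii = 1; ii < mm; ++ii) {
    int i = keep[ii];
    double s;
    while (true) {
      int vk = v[k];
      s = ((f[i] + pos[i] * pos[i]) - (f[vk] + pos[vk] * pos[vk])) /
          (2.0 * pos[i] - 2.0 * pos[vk]);
      if (s <= z[k] && k > 0) { --k; }
      else if (s <= z[k] && k == 0) { v[0] = i; s = -EDT_INF; break; }
      else break;
    }
    if (s == -EDT_INF) { z[0] = -EDT_INF; z[1] = EDT_INF; continue; }
    ++k;
    v[k] = i; z[k] = s; z[k + 1] = EDT_INF;
  }
  int j = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    while (z[j + 1] < q[i]) ++j;
    double d = q[i] - pos[v[j]];
    out[i] = d * d + f[v[j]];
  }
}

// Exact squared Euclidean distance from every TRUE voxel to the nearest
// FALSE voxel (voxel-center metric). FALSE voxels get 0. `periodic` wraps
// all three axes (implemented by triple replication in passes 2 and 3 and
// cyclic scans in pass 1).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims, bool periodic) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  NumericVector d(n);

  // pass 1: along x, distance (not squared) to nearest FALSE in the line
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      int64_t base = vidx(0, y, z, nx, ny);
      double dist = EDT_INF;
      int rep = periodic ? 2 : 1;
      for (int r = 0; r < rep; ++r) {
        for (int x = 0; x < nx; ++x) {
          int64_t v = base + x;
          if (!mask[v]) dist = 0.0; else dist = (dist >= EDT_INF) ? EDT_INF : dist + 1.0;
          if (r == 0) d[v] = dist; else d[v] = std::min(d[v], dist);
        }
      }
      dist = EDT_INF;
      for (int r = 0; r < rep; ++r) {
        for (int x = nx - 1; x >= 0; --x) {
          int64_t v = base + x;
          if (!mask[v]) dist = 0.0; else dist = (dist >= EDT_INF) ? EDT_INF : dist + 1.0;
          if (dist < d[v]) d[v] = dist;
        }
      }
      for (int x = 0; x < nx; ++x) {
        int64_t v = base + x;
        d[v] = (d[v] >= EDT_INF) ? EDT_INF : d[v] * d[v];
      }
    }
  }

  // passes 2 and 3: parabolic envelope along y then z
  for (int axis = 1; axis <= 2; ++axis) {
    int len = (axis == 1) ? ny : nz;
    int m = periodic ? 3 * len : len;
    std::vector<double> f(m), pos(m), out(len), q(len);
    for (int i = 0; i < len; ++i) q[i] = (double)i;
    int64_t stride = (axis == 1) ? nx : (int64_t)nx * ny;
    // iterate over all lines perpendicular to `axis`
    for (int a = 0; a < ((axis == 1) ? nx : nx); ++a) {
      for (int b = 0; b < ((axis == 1) ? nz : ny); ++b) {
        int64_t base = (axis == 1) ? vidx(a, 0, b, nx, ny) : vidx(a, b, 0, nx, ny);
        for (int i = 0; i < m; ++i) {
          int src = periodic ? ((i % len)) : i;
          double offset = periodic ? (double)(i - len) : (double)i;
          f[i] = d[base + stride * src];
          pos[i] = offset;
        }
        bool allinf = true;
        for (int i = 0; i < m; ++i) if (f[i] < EDT_INF) { allinf = false; break; }
        if (allinf) continue;
        edt_1d(f, pos, m, q, out);
        for (int i = 0; i < len; ++i) d[base + stride * i] = out[i];
      }
    }
  }
  return d;
}

// Local thickness by sphere painting: thickness(v) = max radius r(c) over
// phase voxels c whose inscribed sphere (radius r(c), strict interior
// |v - c| < r(c)) covers v. Takes SQUARED radii (exact integers from the
// EDT) to keep the strict comparison exact; rsq = 0 marks out-of-phase
// voxels. Returns radii (square roots) in voxel units.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector rsq, IntegerVector dims, bool periodic) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  std::vector<double> best(n, 0.0);   // squared radii
  std::vector<int64_t> order;
  order.reserve(n);
  for (int64_t i = 0; i < n; ++i) if (rsq[i] > 0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int64_t a, int64_t b) { return rsq[a] > rsq[b]; });
  for (int64_t c : order) {
    const double r2 = rsq[c];
    const int R = (int)std::floor(std::sqrt(r2));
    int x0 = (int)(c % nx), y0 = (int)((c / nx) % ny), z0 = (int)(c / ((int64_t)nx * ny));
    for (int dz = -R; dz <= R; ++dz) {
      int z = z0 + dz;
      if (periodic) z = ((z % nz) + nz) % nz; else if (z < 0 || z >= nz) continue;
      for (int dy = -R; dy <= R; ++dy) {
        int y = y0 + dy;
        if (periodic) y = ((y % ny) + ny) % ny; else if (y < 0 || y >= ny) continue;
        double dd = (double)dz * dz + (double)dy * dy;
        if (dd >= r2) continue;
        for (int dx = -R; dx <= R; ++dx) {
          if (dd + (double)dx * dx >= r2) continue;  // strict interior
          int x = x0 + dx;
          if (periodic) x = ((x % nx) + nx) % nx; else if (x < 0 || x >= nx) continue;
          int64_t v = vidx(x, y, z, nx, ny);
          if (best[v] < r2) best[v] = r2;
        }
      }
    }
  }
  NumericVector out(n);
  for (int64_t i = 0; i < n; ++i) out[i] = std::sqrt(best[i]);
  return out;
}

// Marker-based watershed by priority flooding: basins grow from seeds in
// order of decreasing priority; each masked voxel joins the basin of the
// neighbour through which it was first reached.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, LogicalVector mask,
                            IntegerVector seeds, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  typedef std::pair<double, int64_t> Q;
  std::priority_queue<Q> heap;
  for (int64_t i = 0; i < n; ++i) {
    if (seeds[i] > 0) { lab[i] = seeds[i]; heap.push(Q(priority[i], i)); }
  }
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  while (!heap.empty()) {
    int64_t v = heap.top().second; heap.pop();
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((int64_t)nx * ny));
    for (int d = 0; d < 6; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      int64_t w = vidx(xx, yy, zz, nx, ny);
      if (mask[w] && lab[w] == 0) {
        lab[w] = lab[v];
        heap.push(Q(priority[w], w));
      }
    }
  }
  return lab;
}

// 26-neighbourhood local maxima of `field` restricted to `mask` (plateaus:
// first voxel in scan order wins via strict > against already-found peaks
// handled on the R side; here a voxel is a peak if no neighbour is larger).
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector field, LogicalVector mask,
                               IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  LogicalVector peak(n, false);
  for (int64_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((int64_t)nx * ny));
    bool is_peak = true;
    for (int dz = -1; dz <= 1 && is_peak; ++dz)
      for (int dy = -1; dy <= 1 && is_peak; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          int64_t w = vidx(xx, yy, zz, nx, ny);
          if (field[w] > field[v]) { is_peak = false; break; }
        }
    if (is_peak) peak[v] = true;
  }
  return peak;
}
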