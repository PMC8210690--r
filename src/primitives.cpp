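// Low-level image primitives for 3D stacks stored as R arrays [y, x, z]
// (column-major, so linear index = y + ny*(x + nx*z)).

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".medfilt3_cpp")]]
NumericVector medfilt3_cpp(NumericVector vol, IntegerVector dims,
                           IntegerVector radius) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int ry = radius[0], rx = radius[1], rz = radius[2];
  NumericVector out(vol.size());
  std::vector<double> box;
  box.reserve((2 * ry + 1) * (2 * rx + 1) * (2 * rz + 1));
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        box.clear();
        // edge replication: clamp neighbour indices into the volume
        for (int dz = -rz; dz <= rz; ++dz) {
          const int zz = clampi(z + dz, 0, nz - 1);
          for (int dx = -rx; dx <= rx; ++dx) {
            const int xx = clampi(x + dx, 0, nx - 1);
            for (int dy = -ry; dy <= ry; ++dy) {
              const int yy = clampi(y + dy, 0, ny - 1);
              box.push_back(vol[yy + ny * (xx + (R_xlen_t)nx * zz)]);
            }
          }
        }
        const size_t mid = box.size() / 2; // box size is odd
        std::nth_element(box.begin(), box.begin() + mid, box.end());
        out[y + ny * (x + (R_xlen_t)nx * z)] = box[mid];
      }
    }
  }
  return out;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher),
// applied separably per axis with anisotropic spacing.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  double w) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance transform of a boolean mask: distance (in the units of
// `spacing`, ordered dy, dx, dz) from each true voxel to the nearest false
// voxel. False voxels get 0. Voxels of an all-true volume get distances to
// the (implicit) boundary? No: classic EDT to background only; an all-true
// volume yields Inf, callers guard against that.
// [[Rcpp::export(name = ".edt3_cpp")]]
NumericVector edt3_cpp(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double dy = spacing[0], dx = spacing[1], dz = spacing[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = ny * (x + (R_xlen_t)nx * z);
      for (int y = 0; y < ny; ++y) f[y] = g[base + y];
      edt1d(f, d, dy);
      for (int y = 0; y < ny; ++y) g[base + y] = d[y];
    }
  // along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[y + ny * (x + (R_xlen_t)nx * z)];
      edt1d(f, d, dx);
      for (int x = 0; x < nx; ++x) g[y + ny * (x + (R_xlen_t)nx * z)] = d[x];
    }
  // along z
  f.resize(nz); d.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = g[y + ny * (x + (R_xlen_t)nx * z)];
      edt1d(f, d, dz);
      for (int z = 0; z < nz; ++z) g[y + ny * (x + (R_xlen_t)nx * z)] = d[z];
    }

  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = std::sqrt(g[i]);
  return out;
}

struct QItem {
  double prio;   // distance-transform value: flood high first
  R_xlen_t ord;  // FIFO tie-break for determinism
  R_xlen_t idx;
  int label;
};
struct QLess {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;
    return a.ord > b.ord;
  }
};

// Seeded watershed by Meyer flooding on -dist restricted to mask.
// seeds: integer volume, 0 = unlabelled. 26-connectivity.
// [[Rcpp::export(name = ".watershed_flood_cpp")]]
IntegerVector watershed_flood_cpp(IntegerVector seeds, NumericVector dist,
                                  LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  IntegerVector lab = clone(seeds);
  std::priority_queue<QItem, std::vector<QItem>, QLess> pq;
  R_xlen_t ord = 0;

  auto push_neigh = [&](int y, int x, int z, int label) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dy && !dx && !dz) continue;
          const int yy = y + dy, xx = x + dx, zz = z + dz;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
            continue;
          const R_xlen_t j = yy + ny * (xx + (R_xlen_t)nx * zz);
          if (mask[j] && lab[j] == 0)
            pq.push(QItem{dist[j], ord++, j, label});
        }
  };

  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t i = y + ny * (x + (R_xlen_t)nx * z);
        if (lab[i] > 0) push_neigh(y, x, z, lab[i]);
      }

  while (!pq.empty()) {
    const QItem it = pq.top();
    pq.pop();
    if (lab[it.idx] != 0) continue;
    lab[it.idx] = it.label;
    const int z = (int)(it.idx / ((R_xlen_t)ny * nx));
    const int rem = (int)(it.idx % ((R_xlen_t)ny * nx));
    push_neigh(rem % ny, rem / ny, z, it.label);
  }
  return lab;
}

// 26-connected component labelling of a boolean mask (BFS).
// [[Rcpp::export(name = ".conncomp26_cpp")]]
IntegerVector conncomp26_cpp(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++next;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int z = (int)(cur / ((R_xlen_t)ny * nx));
      const int rem = (int)(cur % ((R_xlen_t)ny * nx));
      const int y = rem % ny, x = rem / ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dy && !dx && !dz) continue;
            const int yy = y + dy, xx = x + dx, zz = z + dz;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
                zz < 0 || zz >= nz)
              continue;
            const R_xlen_t j = yy + ny * (xx + (R_xlen_t)nx * zz);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// Orthogonal projection of 2D points onto a polyline.
// Returns per point: arclength of the nearest point on the polyline,
// perpendicular distance, and a beyond-end flag (+/-1 when the unclamped
// projection onto the terminal segment falls outside it, i.e. the point
// lies past the polyline's upstream (-1) or downstream (+1) end).
// Ties (equidistant segments) resolve to the smaller arclength: segments are
// scanned in order and strictly-smaller distance is required to switch.
// [[Rcpp::export(name = ".project_polyline_cpp")]]
List project_polyline_cpp(NumericVector px, NumericVector py,
                          NumericVector vx, NumericVector vy) {
  const int np = px.size(), ns = vx.size() - 1;
  NumericVector arc(np), dist(np);
  IntegerVector beyond(np);
  std::vector<double> seg_s(ns + 1, 0.0), seg_len(ns);
  for (int k = 0; k < ns; ++k) {
    const double dx = vx[k + 1] - vx[k], dy = vy[k + 1] - vy[k];
    seg_len[k] = std::sqrt(dx * dx + dy * dy);
    seg_s[k + 1] = seg_s[k] + seg_len[k];
  }
  for (int i = 0; i < np; ++i) {
    double best_d2 = std::numeric_limits<double>::infinity();
    double best_s = 0.0;
    double t_first = 0.0, t_last = 0.0;
    for (int k = 0; k < ns; ++k) {
      const double ax = vx[k], ay = vy[k];
      const double dx = vx[k + 1] - ax, dy = vy[k + 1] - ay;
      double t = ((px[i] - ax) * dx + (py[i] - ay) * dy) /
                 (seg_len[k] * seg_len[k]);
      if (k == 0) t_first = t;
      if (k == ns - 1) t_last = t;
      const double tc = t < 0 ? 0 : (t > 1 ? 1 : t);
      const double cx = ax + tc * dx, cy = ay + tc * dy;
      const double d2 = (px[i] - cx) * (px[i] - cx) +
                        (py[i] - cy) * (py[i] - cy);
      if (d2 < best_d2 - 1e-12) {
        best_d2 = d2;
        best_s = seg_s[k] + tc * seg_len[k];
      }
    }
    arc[i] = best_s;
    dist[i] = std::sqrt(best_d2);
    beyond[i] = 0;
    if (best_s <= 0.0 && t_first < 0) beyond[i] = -1;
    if (best_s >= seg_s[ns] && t_last > 1) beyond[i] = 1;
  }
  return List::create(_["arclength"] = arc, _["distance"] = dist,
                      _["beyond"] = beyond);
}
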