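// Low-level voxel kernels: Euclidean distance transform, connected-component
// labeling, fuzzy distance transform, topology-preserving fuzzy thinning,
// local digital-topology numbers, and fuzzy-boundary ray casting.
//
// Conventions: volumes are R arrays in column-major order, voxel (x,y,z)
// at linear index x + nx*(y + ny*z) (0-based here, 1-based in R).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
#include <limits>
#include <algorithm>
#include <functional>
#include <unordered_map>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher), anisotropic.
// f: sampled function (finite; a large sentinel stands for "no site"),
// h: sample spacing. Result written to d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = h2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest voxel
// where mask == 0 (i.e. distance-to-background inside the mask; background
// voxels get 0). Separable 3D transform with per-axis spacing. If the mask
// has no background at all, values saturate at a large sentinel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double ex = nx * spacing[0], ey = ny * spacing[1],
               ez = nz * spacing[2];
  const double BIG = 4.0 * (ex * ex + ey * ey + ez * ez) + 1.0;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, d;
  // along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * (R_xlen_t)z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = out[base + nxy * z];
      dt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + nxy * z] = d[z];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (6 or 26 connectivity), union-find.
// Labels are 1..K in decreasing component size? No: arbitrary; sizes returned.
// [[Rcpp::export]]
List cpp_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> parent(n, -1);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };

  // neighbor offsets over "previous" half-space
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[i]) continue;
        parent[i] = (int)i;
        for (auto& o : offs) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          if (mask[j]) unite((int)i, (int)j);
        }
      }

  IntegerVector labels(n, 0);
  std::unordered_map<int,int> remap;
  std::vector<double> sizes;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = find((int)i);
    auto it = remap.find(r);
    int lab;
    if (it == remap.end()) { lab = ++next; remap[r] = lab; sizes.push_back(0); }
    else lab = it->second;
    labels[i] = lab;
    sizes[lab - 1] += 1;
  }
  return List::create(_["labels"] = labels,
                      _["sizes"] = NumericVector(sizes.begin(), sizes.end()));
}

// ---------------------------------------------------------------------------
// Fuzzy distance transform (Saha et al.): shortest path cost from each
// support voxel (membership > 0 within `support`) to the complement, with
// step cost = mean membership of the two endpoints * physical step length.
// Dijkstra over the 26-neighborhood.
// [[Rcpp::export]]
NumericVector cpp_fdt(NumericVector membership, LogicalVector support,
                      IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector dist(n);
  for (R_xlen_t i = 0; i < n; ++i) dist[i] = support[i] ? INF : 0.0;

  struct Node { double d; R_xlen_t i; };
  struct Cmp { bool operator()(const Node& a, const Node& b) const {
    return a.d > b.d; } };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;

  std::vector<std::array<int,3>> offs;
  std::vector<double> steplen;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        offs.push_back({dx, dy, dz});
        steplen.push_back(std::sqrt(dx * dx * spacing[0] * spacing[0] +
                                    dy * dy * spacing[1] * spacing[1] +
                                    dz * dz * spacing[2] * spacing[2]));
      }

  // seed: support voxels adjacent to the complement (or the volume edge)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!support[i]) continue;
        double best = INF;
        for (size_t k = 0; k < offs.size(); ++k) {
          int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
          double mu_out = 0.0;
          bool outside;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
            outside = true;
          } else {
            R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            outside = !support[j];
            if (outside) mu_out = membership[j];
          }
          if (outside) {
            // half step from the support interface to this voxel's center,
            // traversed at this voxel's own membership
            (void)mu_out;
            double c = membership[i] * steplen[k] * 0.5;
            if (c < best) best = c;
          }
        }
        if (best < INF) { dist[i] = best; pq.push({best, i}); }
      }

  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    if (nd.d > dist[nd.i]) continue;
    int x = (int)(nd.i % nx);
    int y = (int)((nd.i / nx) % ny);
    int z = (int)(nd.i / ((R_xlen_t)nx * ny));
    for (size_t k = 0; k < offs.size(); ++k) {
      int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!support[j]) continue;
      double c = nd.d + 0.5 * (membership[nd.i] + membership[j]) * steplen[k];
      if (c < dist[j] - 1e-12) { dist[j] = c; pq.push({c, j}); }
    }
  }
  return dist;
}

// ---------------------------------------------------------------------------
// Rigid resampling with Lanczos windowed-sinc interpolation: output voxel
// at physical p maps to input position q = R^T (p - c) + c (pull-back of
// the rotation sending the anatomy axis to +z). `a` is the Lanczos window
// radius in voxels. Out-of-range positions get `fill`.
static inline double lanczos1(double u, int a) {
  if (u == 0.0) return 1.0;
  double au = std::fabs(u);
  if (au >= a) return 0.0;
  double pu = M_PI * u;
  return a * std::sin(pu) * std::sin(pu / a) / (pu * pu);
}

// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericMatrix rot,
                                 NumericVector center, int a, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // q = rot^T (p - c) + c, row-major loop over output voxels
  double R[3][3];
  for (int r = 0; r < 3; ++r)
    for (int cc = 0; cc < 3; ++cc) R[r][cc] = rot(r, cc);
  std::vector<double> wx(2 * a), wy(2 * a), wz(2 * a);
  for (int z = 0; z < nz; ++z) {
    double pz = z * spacing[2] - center[2];
    for (int y = 0; y < ny; ++y) {
      double py = y * spacing[1] - center[1];
      for (int x = 0; x < nx; ++x) {
        double px = x * spacing[0] - center[0];
        // rot^T * p
        double qx = (R[0][0] * px + R[1][0] * py + R[2][0] * pz +
                     center[0]) / spacing[0];
        double qy = (R[0][1] * px + R[1][1] * py + R[2][1] * pz +
                     center[1]) / spacing[1];
        double qz = (R[0][2] * px + R[1][2] * py + R[2][2] * pz +
                     center[2]) / spacing[2];
        R_xlen_t oi = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        int ix = (int)std::floor(qx), iy = (int)std::floor(qy),
            iz = (int)std::floor(qz);
        if (ix - a + 1 < 0 || iy - a + 1 < 0 || iz - a + 1 < 0 ||
            ix + a >= nx || iy + a >= ny || iz + a >= nz) {
          // near the border fall back to trilinear (clamped) or fill
          if (qx < 0 || qy < 0 || qz < 0 || qx > nx - 1 || qy > ny - 1 ||
              qz > nz - 1) {
            out[oi] = fill;
          } else {
            int x0 = std::min(ix, nx - 2), y0 = std::min(iy, ny - 2),
                z0 = std::min(iz, nz - 2);
            x0 = std::max(x0, 0); y0 = std::max(y0, 0); z0 = std::max(z0, 0);
            double fx = qx - x0, fy = qy - y0, fz = qz - z0;
            auto at = [&](int aa, int bb, int cc) {
              return vol[aa + (R_xlen_t)nx * (bb + (R_xlen_t)ny * cc)];
            };
            double c00 = at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx;
            double c10 = at(x0, y0 + 1, z0) * (1 - fx) +
                         at(x0 + 1, y0 + 1, z0) * fx;
            double c01 = at(x0, y0, z0 + 1) * (1 - fx) +
                         at(x0 + 1, y0, z0 + 1) * fx;
            double c11 = at(x0, y0 + 1, z0 + 1) * (1 - fx) +
                         at(x0 + 1, y0 + 1, z0 + 1) * fx;
            out[oi] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                      (c01 * (1 - fy) + c11 * fy) * fz;
          }
          continue;
        }
        double sx = 0, sy = 0, sz = 0;
        for (int k = 0; k < 2 * a; ++k) {
          wx[k] = lanczos1(qx - (ix - a + 1 + k), a); sx += wx[k];
          wy[k] = lanczos1(qy - (iy - a + 1 + k), a); sy += wy[k];
          wz[k] = lanczos1(qz - (iz - a + 1 + k), a); sz += wz[k];
        }
        double acc = 0;
        for (int kz = 0; kz < 2 * a; ++kz) {
          if (wz[kz] == 0) continue;
          double accy = 0;
          for (int ky = 0; ky < 2 * a; ++ky) {
            if (wy[ky] == 0) continue;
            double accx = 0;
            R_xlen_t base = (R_xlen_t)nx * ((iy - a + 1 + ky) +
                            (R_xlen_t)ny * (iz - a + 1 + kz)) + ix - a + 1;
            for (int kx = 0; kx < 2 * a; ++kx)
              accx += wx[kx] * vol[base + kx];
            accy += wy[ky] * accx;
          }
          acc += wz[kz] * accy;
        }
        out[oi] = acc / (sx * sy * sz);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seeded geodesic (chamfer) distance: Dijkstra over the 26-neighborhood
// restricted to `region`, starting from `seed_idx` (0-based) at
// `seed_val`. Unreached voxels (and voxels outside the region that are not
// seeds) return Inf. Used for subvoxel-accurate signed distance fields:
// seeds carry interpolated distances to a fuzzy boundary.
// [[Rcpp::export]]
NumericVector cpp_geodesic_dist(LogicalVector region, IntegerVector dim,
                                NumericVector spacing,
                                IntegerVector seed_idx,
                                NumericVector seed_val) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector dist(n, INF);

  struct Node { double d; R_xlen_t i; };
  struct Cmp { bool operator()(const Node& a, const Node& b) const {
    return a.d > b.d; } };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  for (int k = 0; k < seed_idx.size(); ++k) {
    R_xlen_t i = seed_idx[k];
    if (seed_val[k] < dist[i]) { dist[i] = seed_val[k]; pq.push({dist[i], i}); }
  }

  std::vector<std::array<int,3>> offs;
  std::vector<double> steplen;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        offs.push_back({dx, dy, dz});
        steplen.push_back(std::sqrt(dx * dx * spacing[0] * spacing[0] +
                                    dy * dy * spacing[1] * spacing[1] +
                                    dz * dz * spacing[2] * spacing[2]));
      }

  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    if (nd.d > dist[nd.i]) continue;
    int x = (int)(nd.i % nx);
    int y = (int)((nd.i / nx) % ny);
    int z = (int)(nd.i / ((R_xlen_t)nx * ny));
    for (size_t k = 0; k < offs.size(); ++k) {
      int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!region[j]) continue;
      double c = nd.d + steplen[k];
      if (c < dist[j] - 1e-12) { dist[j] = c; pq.push({c, j}); }
    }
  }
  return dist;
}

// ---------------------------------------------------------------------------
// Digital topology helpers on a 3x3x3 neighborhood.
// nb: 27 bools, index (dx+1) + 3*(dy+1) + 9*(dz+1); center nb[13].

// number of 26-connected object components among the 26 neighbors
static int t26_object(const bool* nb) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack = {s};
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2)
              continue;
            int q = xx + 3 * yy + 9 * zz;
            if (q == 13 || seen[q] || !nb[q]) continue;
            seen[q] = true;
            stack.push_back(q);
          }
    }
  }
  return comps;
}

// number of 6-connected background components within the 18-neighborhood
// (no face-adjacency requirement; used for classification, where an
// oblique digital surface may expose one side only through edge voxels)
static int t6_background_all(const bool* nb) {
  auto in18 = [](int s) {
    int dx = std::abs(s % 3 - 1), dy = std::abs((s / 3) % 3 - 1),
        dz = std::abs(s / 9 - 1);
    int cheb = std::max(dx, std::max(dy, dz));
    return (cheb >= 1) && (dx + dy + dz <= 2);
  };
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || nb[s] || seen[s] || !in18(s)) continue;
    ++comps;
    std::vector<int> stack = {s};
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = cx + d6[k][0], yy = cy + d6[k][1], zz = cz + d6[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int q = xx + 3 * yy + 9 * zz;
        if (q == 13 || seen[q] || nb[q] || !in18(q)) continue;
        seen[q] = true;
        stack.push_back(q);
      }
    }
  }
  return comps;
}

// number of 6-connected background components within the 18-neighborhood
// that are 6-adjacent to the center
static int t6_background(const bool* nb) {
  auto in18 = [](int s) {
    int dx = std::abs(s % 3 - 1), dy = std::abs((s / 3) % 3 - 1),
        dz = std::abs(s / 9 - 1);
    int cheb = std::max(dx, std::max(dy, dz));
    return (cheb >= 1) && (dx + dy + dz <= 2);
  };
  bool seen[27] = {false};
  int comps = 0;
  static const int face[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  for (int fi = 0; fi < 6; ++fi) {
    int s = face[fi];
    if (nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack = {s};
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = cx + d6[k][0], yy = cy + d6[k][1], zz = cz + d6[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int q = xx + 3 * yy + 9 * zz;
        if (q == 13 || seen[q] || nb[q] || !in18(q)) continue;
        seen[q] = true;
        stack.push_back(q);
      }
    }
  }
  return comps;
}

static void fill_neighborhood(const std::vector<char>& obj, int nx, int ny,
                              int nz, int x, int y, int z, bool* nb) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = false;
        if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          v = obj[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] != 0;
        nb[(dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)] = v;
      }
}

static bool is_simple(const std::vector<char>& obj, int nx, int ny, int nz,
                      int x, int y, int z) {
  bool nb[27];
  fill_neighborhood(obj, nx, ny, nz, x, y, z, nb);
  return t26_object(nb) == 1 && t6_background(nb) == 1;
}

// ---------------------------------------------------------------------------
// Fuzzy skeletonization: ordered topology-preserving erosion of the support
// (membership >= 0.5), visiting voxels in increasing fuzzy-distance order
// (ties broken by linear index), deleting only simple points, and retaining
// fuzzy-medial anchors (voxels with no strictly larger FDT neighbor).
// Repeats passes until stable; the result is a thin set of medial surfaces
// and curves.
// [[Rcpp::export]]
LogicalVector cpp_fuzzy_thin(LogicalVector support, NumericVector fdt,
                             IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> obj(n, 0);
  std::vector<R_xlen_t> idx;
  for (R_xlen_t i = 0; i < n; ++i)
    if (support[i]) { obj[i] = 1; idx.push_back(i); }

  const double tol = 0.5 * std::min(spacing[0],
                        std::min(spacing[1], spacing[2]));

  // anchors (fuzzy-medial voxels): local maxima of the FDT over the
  // 26-neighborhood, with ties tolerated (a tied ridge such as a medial
  // plane stays anchored as a whole). One pathology is suppressed: where
  // the medial layer is exactly two voxels thick (both layers tie in FDT
  // and both border the background), the layer whose tying face-neighbor
  // wins the linear-index comparison keeps the anchor and the other is
  // demoted, so the skeleton thins to a single deterministic layer.
  auto fdt_of = [&](int x, int y, int z) -> double {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
      return -1.0;
    R_xlen_t j = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
    return obj[j] ? fdt[j] : -1.0;
  };
  std::vector<char> anchor(n, 0);
  for (R_xlen_t i : idx) {
    int x = (int)(i % nx), y = (int)((i / nx) % ny),
        z = (int)(i / ((R_xlen_t)nx * ny));
    bool localmax = true;
    for (int dz = -1; dz <= 1 && localmax; ++dz)
      for (int dy = -1; dy <= 1 && localmax; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          if (fdt_of(x + dx, y + dy, z + dz) > fdt[i] + tol) {
            localmax = false;
            break;
          }
        }
    if (!localmax) { anchor[i] = 0; continue; }
    // double-layer suppression along each grid axis
    bool demoted = false;
    const int ax[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int a = 0; a < 3 && !demoted; ++a)
      for (int s = -1; s <= 1 && !demoted; s += 2) {
        double back = fdt_of(x - s * ax[a][0], y - s * ax[a][1],
                             z - s * ax[a][2]);
        if (back >= fdt[i] - tol) continue;         // not a boundary side
        int ux = x + s * ax[a][0], uy = y + s * ax[a][1],
            uz = z + s * ax[a][2];
        double tie = fdt_of(ux, uy, uz);
        if (tie < fdt[i] - tol || tie > fdt[i] + tol) continue;  // no tie
        R_xlen_t j = ux + (R_xlen_t)nx * (uy + (R_xlen_t)ny * uz);
        if (j <= i) continue;                        // v wins the tie
        double ufar = fdt_of(ux + s * ax[a][0], uy + s * ax[a][1],
                             uz + s * ax[a][2]);
        if (ufar < fdt[i] - tol) demoted = true;     // u is the far layer
      }
    anchor[i] = demoted ? 0 : 1;
  }

  std::sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (fdt[a] != fdt[b]) return fdt[a] < fdt[b];
    return a < b;
  });

  bool changed = true;
  while (changed) {
    changed = false;
    for (R_xlen_t i : idx) {
      if (!obj[i] || anchor[i]) continue;
      int x = (int)(i % nx), y = (int)((i / nx) % ny),
          z = (int)(i / ((R_xlen_t)nx * ny));
      if (is_simple(obj, nx, ny, nz, x, y, z)) {
        obj[i] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n, false);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = obj[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Local topological numbers for every object voxel: neighbor count,
// object 26-component count (xi) and background 6-component count (eta).
// [[Rcpp::export]]
List cpp_topo_numbers(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> obj(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) obj[i] = mask[i] ? 1 : 0;
  IntegerVector nnbr(n, NA_INTEGER), xi(n, NA_INTEGER), eta(n, NA_INTEGER),
      eta_all(n, NA_INTEGER);
  bool nb[27];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!obj[i]) continue;
        fill_neighborhood(obj, nx, ny, nz, x, y, z, nb);
        int cnt = 0;
        for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++cnt;
        nnbr[i] = cnt;
        xi[i] = t26_object(nb);
        eta[i] = t6_background(nb);
        eta_all[i] = t6_background_all(nb);
      }
  return List::create(_["nnbr"] = nnbr, _["xi"] = xi, _["eta"] = eta,
                      _["eta_all"] = eta_all);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation of `field` at physical point p (mm, origin at
// voxel (0,0,0) center). Out-of-bounds returns `fill`.
static double trilin(const NumericVector& field, int nx, int ny, int nz,
                     const NumericVector& spacing, double px, double py,
                     double pz, double fill) {
  double gx = px / spacing[0], gy = py / spacing[1], gz = pz / spacing[2];
  int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy),
      z0 = (int)std::floor(gz);
  if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= nx - 1 || y0 >= ny - 1 ||
      z0 >= nz - 1)
    return fill;
  double fx = gx - x0, fy = gy - y0, fz = gz - z0;
  auto at = [&](int a, int b, int c) {
    return field[a + (R_xlen_t)nx * (b + (R_xlen_t)ny * c)];
  };
  double c00 = at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx;
  double c10 = at(x0, y0 + 1, z0) * (1 - fx) + at(x0 + 1, y0 + 1, z0) * fx;
  double c01 = at(x0, y0, z0 + 1) * (1 - fx) + at(x0 + 1, y0, z0 + 1) * fx;
  double c11 = at(x0, y0 + 1, z0 + 1) * (1 - fx) + at(x0 + 1, y0 + 1, z0 + 1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// From each point (voxel indices, 0-based, rows of `pts`), march along each
// direction (rows of `dirs`, unit vectors in physical space) in steps of
// `step` mm until the interpolated field drops below `threshold` or the
// distance exceeds `maxlen`. Returns distances for +dir and -dir with a
// linear subvoxel estimate of the crossing. Censored rays return maxlen.
// [[Rcpp::export]]
List cpp_cast_rays(NumericVector field, IntegerVector dim,
                   NumericVector spacing, NumericMatrix pts,
                   NumericMatrix dirs, double step, double maxlen,
                   double threshold) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = pts.nrow(), nd = dirs.nrow();
  NumericMatrix dpos(np, nd), dneg(np, nd);
  for (int p = 0; p < np; ++p) {
    double ox = pts(p, 0) * spacing[0];
    double oy = pts(p, 1) * spacing[1];
    double oz = pts(p, 2) * spacing[2];
    for (int d = 0; d < nd; ++d) {
      for (int sgn = 0; sgn < 2; ++sgn) {
        double ux = dirs(d, 0), uy = dirs(d, 1), uz = dirs(d, 2);
        if (sgn) { ux = -ux; uy = -uy; uz = -uz; }
        double prev = trilin(field, nx, ny, nz, spacing, ox, oy, oz, 0.0);
        double t = 0.0, hit = maxlen;
        while (t < maxlen) {
          double tn = t + step;
          double v = trilin(field, nx, ny, nz, spacing, ox + tn * ux,
                            oy + tn * uy, oz + tn * uz, threshold - 1.0);
          if (v < threshold) {
            double frac = (prev - threshold) / (prev - v);
            if (frac < 0) frac = 0; if (frac > 1) frac = 1;
            hit = t + frac * step;
            break;
          }
          prev = v;
          t = tn;
        }
        if (sgn) dneg(p, d) = hit; else dpos(p, d) = hit;
      }
    }
  }
  return List::create(_["dpos"] = dpos, _["dneg"] = dneg);
}
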