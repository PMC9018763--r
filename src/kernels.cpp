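#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Array layouts (column-major, matching R):
//   feature maps: dim = (C, D, H, W)  -> index c + C*(z + D*(y + H*x))
//   conv weights: dim = (Cout, Cin, k, k, k)
//   plain volumes: dim = (D, H, W)    -> index z + D*(y + H*x)

// ---------------------------------------------------------------------------
// Anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher,
// separable lower-envelope method with per-axis physical spacing).
// Input: logical mask (D,H,W); output: distance in mm to the nearest TRUE
// voxel (0 on TRUE voxels, Inf if mask empty).
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double s) {
  // d(p) = min_q ( (s*(p-q))^2 + f(q) ); entries with f = +Inf cannot carry
  // the minimum and are skipped when building the lower envelope.
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double s2 = s * s;
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int kk = 0;
  v[0] = q0; z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double sq = s2 * q * q;
    while (true) {
      int vk = v[kk];
      double sv = (f[q] + sq - (f[vk] + s2 * vk * vk)) / (2.0 * s2 * (q - vk));
      if (kk > 0 && sv <= z[kk]) { --kk; }
      else { ++kk; v[kk] = q; z[kk] = sv; z[kk + 1] = INF; break; }
    }
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = s * (q - v[kk]);
    d[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector edt3d(LogicalVector mask, int D, int H, int W, NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(static_cast<R_xlen_t>(D) * H * W);
  double* op = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) op[i] = mask[i] ? 0.0 : INF;
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  std::vector<double> f(std::max(D, std::max(H, W))), d(std::max(D, std::max(H, W)));
  // along z
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      size_t base = (size_t)D * (y + (size_t)H * x);
      bool any = false;
      for (int z = 0; z < D; ++z) { f[z] = op[base + z]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, D, sz);
      for (int z = 0; z < D; ++z) op[base + z] = d[z];
    }
  // along y
  for (int x = 0; x < W; ++x)
    for (int z = 0; z < D; ++z) {
      bool any = false;
      for (int y = 0; y < H; ++y) { f[y] = op[z + (size_t)D * (y + (size_t)H * x)]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, H, sy);
      for (int y = 0; y < H; ++y) op[z + (size_t)D * (y + (size_t)H * x)] = d[y];
    }
  // along x
  for (int y = 0; y < H; ++y)
    for (int z = 0; z < D; ++z) {
      bool any = false;
      for (int x = 0; x < W; ++x) { f[x] = op[z + (size_t)D * (y + (size_t)H * x)]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, W, sx);
      for (int x = 0; x < W; ++x) op[z + (size_t)D * (y + (size_t)H * x)] = d[x];
    }
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (op[i] < INF) op[i] = std::sqrt(op[i]);
  out.attr("dim") = IntegerVector::create(D, H, W);
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (26- or 6-connectivity), BFS.
// Returns integer labels 0 (background), 1..n.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cc3d(LogicalVector mask, int D, int H, int W, int connectivity) {
  IntegerVector lab(static_cast<R_xlen_t>(D) * H * W);
  int next = 0;
  std::vector<std::array<int,3>> nb;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dz, dy, dx});
      }
  std::queue<size_t> q;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      for (int z = 0; z < D; ++z) {
        size_t idx = z + (size_t)D * (y + (size_t)H * x);
        if (!mask[idx] || lab[idx] != 0) continue;
        lab[idx] = ++next;
        q.push(idx);
        while (!q.empty()) {
          size_t cur = q.front(); q.pop();
          int cz = cur % D, cy = (cur / D) % H, cx = cur / ((size_t)D * H);
          for (auto& o : nb) {
            int nz = cz + o[0], ny = cy + o[1], nx = cx + o[2];
            if (nz < 0 || nz >= D || ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            size_t ni = nz + (size_t)D * (ny + (size_t)H * nx);
            if (mask[ni] && lab[ni] == 0) { lab[ni] = next; q.push(ni); }
          }
        }
      }
  lab.attr("dim") = IntegerVector::create(D, H, W);
  return lab;
}

// ---------------------------------------------------------------------------
// 3D curve thinning: sequential deletion of simple border points, six
// directional subiterations per cycle (U, D, N, S, E, W), endpoints kept.
// Simple-point test after Malandain & Bertrand: exactly one 26-component of
// foreground in N26 adjacent to the center, and exactly one 6-component of
// background in N18 6-adjacent to the center.
// ---------------------------------------------------------------------------

static inline int nidx(int dz, int dy, int dx) { return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1)); }

static bool is_simple(const std::vector<char>& m, int D, int H, int W, int z, int y, int x) {
  char fg[27]; // 3x3x3 neighborhood, center at nidx(0,0,0)=13
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int nz = z + dz, ny = y + dy, nx = x + dx;
        char v = 0;
        if (nz >= 0 && nz < D && ny >= 0 && ny < H && nx >= 0 && nx < W)
          v = m[nz + (size_t)D * (ny + (size_t)H * nx)];
        fg[nidx(dz, dy, dx)] = v;
      }
  // --- count 26-components of foreground in N26 (center excluded) ---
  int comp26 = 0;
  char vis[27] = {0};
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !fg[i] || vis[i]) continue;
    ++comp26;
    if (comp26 > 1) return false;
    // BFS within neighborhood
    std::array<int, 27> st; int sp = 0;
    st[sp++] = i; vis[i] = 1;
    while (sp) {
      int cur = st[--sp];
      int cz = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cx = cur / 9 - 1;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int nz = cz + dz, ny = cy + dy, nx = cx + dx;
            if (nz < -1 || nz > 1 || ny < -1 || ny > 1 || nx < -1 || nx > 1) continue;
            int ni = nidx(nz, ny, nx);
            if (ni == 13 || !fg[ni] || vis[ni]) continue;
            vis[ni] = 1; st[sp++] = ni;
          }
    }
  }
  if (comp26 != 1) return false;
  // --- count 6-components of background in N18 that are 6-adjacent to center ---
  // N18: neighbors with |dz|+|dy|+|dx| <= 2 (excluding center)
  auto inN18 = [](int dz, int dy, int dx) {
    int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
    return manh >= 1 && manh <= 2;
  };
  int comp6 = 0;
  char vis2[27] = {0};
  for (int sx = -1; sx <= 1; ++sx)
    for (int sy = -1; sy <= 1; ++sy)
      for (int sz = -1; sz <= 1; ++sz) {
        if (std::abs(sz) + std::abs(sy) + std::abs(sx) != 1) continue; // seeds: 6-neighbors
        int si = nidx(sz, sy, sx);
        if (fg[si] || vis2[si]) continue;
        ++comp6;
        if (comp6 > 1) return false;
        std::array<int, 27> st; int sp = 0;
        st[sp++] = si; vis2[si] = 1;
        while (sp) {
          int cur = st[--sp];
          int cz = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cx = cur / 9 - 1;
          const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
          for (auto& o : d6) {
            int nz = cz + o[0], ny = cy + o[1], nx = cx + o[2];
            if (nz < -1 || nz > 1 || ny < -1 || ny > 1 || nx < -1 || nx > 1) continue;
            if (!inN18(nz, ny, nx)) continue;
            int ni = nidx(nz, ny, nx);
            if (fg[ni] || vis2[ni]) continue;
            vis2[ni] = 1; st[sp++] = ni;
          }
        }
      }
  return comp6 == 1;
}

static int count_fg_neighbors(const std::vector<char>& m, int D, int H, int W, int z, int y, int x) {
  int n = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        int nz = z + dz, ny = y + dy, nx = x + dx;
        if (nz < 0 || nz >= D || ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
        if (m[nz + (size_t)D * (ny + (size_t)H * nx)]) ++n;
      }
  return n;
}

// [[Rcpp::export]]
LogicalVector thin3d(LogicalVector mask, int D, int H, int W) {
  std::vector<char> m(static_cast<size_t>(D) * H * W);
  for (size_t i = 0; i < m.size(); ++i) m[i] = mask[i] ? 1 : 0;
  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}}; // (dz,dy,dx)
  bool changed = true;
  while (changed) {
    changed = false;
    for (auto& dir : dirs) {
      std::vector<size_t> cand;
      for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y)
          for (int z = 0; z < D; ++z) {
            size_t idx = z + (size_t)D * (y + (size_t)H * x);
            if (!m[idx]) continue;
            int nz = z + dir[0], ny = y + dir[1], nx = x + dir[2];
            bool borderDir = (nz < 0 || nz >= D || ny < 0 || ny >= H || nx < 0 || nx >= W) ||
                             !m[nz + (size_t)D * (ny + (size_t)H * nx)];
            if (!borderDir) continue;
            cand.push_back(idx);
          }
      for (size_t idx : cand) {
        int z = idx % D, y = (idx / D) % H, x = idx / ((size_t)D * H);
        if (count_fg_neighbors(m, D, H, W, z, y, x) <= 1) continue; // endpoint
        if (is_simple(m, D, H, W, z, y, x)) { m[idx] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(mask.size());
  for (size_t i = 0; i < m.size(); ++i) out[i] = m[i] != 0;
  out.attr("dim") = IntegerVector::create(D, H, W);
  return out;
}

// ---------------------------------------------------------------------------
// Density-peaks clustering (cutoff kernel).
// points: n x 3 matrix. rho_i = #{j != i : d_ij <= dc}. delta_i = distance to
// nearest point of higher density (ties broken by lower index); global max
// gets max distance. Centers: rho >= min_density & delta >= min_sep. Labels
// propagate from each point's nearest denser neighbor, in decreasing rho.
// Returns list(rho, delta, nneigh (1-based, 0 = none), centers (1-based),
// labels (1-based cluster ids, 0 = unassigned)).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List dpc_cluster(NumericMatrix pts, double dc, double min_density, double min_sep) {
  const int n = pts.nrow();
  NumericVector rho(n), delta(n);
  IntegerVector nneigh(n), labels(n), ord(n);
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { pz[i] = pts(i, 0); py[i] = pts(i, 1); px[i] = pts(i, 2); }
  const double dc2 = dc * dc;
  std::vector<int> cnt(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dz = pz[i] - pz[j], dy = py[i] - py[j], dx = px[i] - px[j];
      if (dz * dz + dy * dy + dx * dx <= dc2) { ++cnt[i]; ++cnt[j]; }
    }
  for (int i = 0; i < n; ++i) rho[i] = cnt[i];
  // "denser" ordering: higher rho, ties by lower index
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (rho[a] != rho[b]) return rho[a] > rho[b];
    return a < b;
  });
  for (int r = 0; r < n; ++r) {
    int i = idx[r];
    ord[r] = i + 1;
    double best = std::numeric_limits<double>::infinity();
    int bestj = -1;
    for (int s = 0; s < r; ++s) { // all points denser than i
      int j = idx[s];
      double dz = pz[i] - pz[j], dy = py[i] - py[j], dx = px[i] - px[j];
      double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < best) { best = d2; bestj = j; }
    }
    if (bestj < 0) {
      // global density maximum: delta = max distance to any point
      double mx = 0.0;
      for (int j = 0; j < n; ++j) {
        double dz = pz[i] - pz[j], dy = py[i] - py[j], dx = px[i] - px[j];
        double d2 = dz * dz + dy * dy + dx * dx;
        if (d2 > mx) mx = d2;
      }
      delta[i] = std::sqrt(mx);
      nneigh[i] = 0;
    } else {
      delta[i] = std::sqrt(best);
      nneigh[i] = bestj + 1;
    }
  }
  // centers: density floor plus either separation or being the densest point
  // (the global maximum must seed a cluster, e.g. a single tight blob)
  std::vector<int> centers;
  for (int i = 0; i < n; ++i)
    if (rho[i] >= min_density && (delta[i] >= min_sep || nneigh[i] == 0))
      centers.push_back(i);
  // assignment in decreasing density order
  for (int i = 0; i < n; ++i) labels[i] = 0;
  int cl = 0;
  for (int c : centers) labels[c] = ++cl;
  for (int r = 0; r < n; ++r) {
    int i = idx[r];
    if (labels[i] == 0 && nneigh[i] > 0) labels[i] = labels[nneigh[i] - 1];
  }
  IntegerVector cen(centers.size());
  for (size_t i = 0; i < centers.size(); ++i) cen[i] = centers[i] + 1;
  return List::create(_["rho"] = rho, _["delta"] = delta, _["nneigh"] = nneigh,
                      _["centers"] = cen, _["labels"] = labels);
}
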