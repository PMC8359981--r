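#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

// Voxel topology helpers for (26,6) digital topology: foreground is
// 26-connected, background 6-connected. A voxel is "simple" iff deleting it
// leaves both the foreground and background topology unchanged; the
// Bertrand-Malandain characterization reduces this to two local component
// counts inside the 3x3x3 neighbourhood.

static inline int idx3(int x, int y, int z, int K, int M) {
  return x + K * (y + M * z);
}

// Collect the 3x3x3 neighbourhood (center excluded) of voxel p as 26 flags.
// Out-of-volume voxels are background.
static inline void neighbourhood(const int *img, int x, int y, int z,
                                 int K, int M, int N, int *nb) {
  int c = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= K || yy >= M || zz >= N)
          nb[c] = 0;
        else
          nb[c] = img[idx3(xx, yy, zz, K, M)];
        c++;
      }
}

// offset tables for the 26-neighbourhood, filled once
static int OFF[26][3];
static bool off_init = false;
static void init_offsets() {
  if (off_init) return;
  int c = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        OFF[c][0] = dx; OFF[c][1] = dy; OFF[c][2] = dz; c++;
      }
  off_init = true;
}

static inline int cheb(const int *a, const int *b) {
  int m = abs(a[0] - b[0]);
  int t = abs(a[1] - b[1]); if (t > m) m = t;
  t = abs(a[2] - b[2]); if (t > m) m = t;
  return m;
}
static inline int manh(const int *a, const int *b) {
  return abs(a[0] - b[0]) + abs(a[1] - b[1]) + abs(a[2] - b[2]);
}

// T26: number of 26-connected components of foreground within the punctured
// neighbourhood. All 26 positions touch the center, so no geodesic filter
// is needed.
static int t26(const int *nb) {
  init_offsets();
  int comp[26]; for (int i = 0; i < 26; i++) comp[i] = -1;
  int ncomp = 0;
  for (int i = 0; i < 26; i++) {
    if (!nb[i] || comp[i] >= 0) continue;
    // BFS
    std::queue<int> q; q.push(i); comp[i] = ncomp;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v = 0; v < 26; v++) {
        if (!nb[v] || comp[v] >= 0) continue;
        if (cheb(OFF[u], OFF[v]) == 1) { comp[v] = ncomp; q.push(v); }
      }
    }
    ncomp++;
  }
  return ncomp;
}

// T6: number of 6-connected components of background within the
// 18-neighbourhood (corners excluded) that are 6-adjacent to the center.
static const int ZERO3[3] = {0, 0, 0};

static int t6(const int *nb) {
  init_offsets();
  int comp[26]; for (int i = 0; i < 26; i++) comp[i] = -1;
  int ncomp = 0;
  for (int i = 0; i < 26; i++) {
    int m0 = manh(OFF[i], ZERO3);
    if (m0 > 2) continue;          // corner: not in N18
    if (nb[i] || comp[i] >= 0) continue;
    if (m0 != 1) {
      // only seed components from face neighbours; edge voxels join by BFS
      continue;
    }
    std::queue<int> q; q.push(i); comp[i] = ncomp;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v = 0; v < 26; v++) {
        int mv = manh(OFF[v], ZERO3);
        if (mv > 2) continue;
        if (nb[v] || comp[v] >= 0) continue;
        if (manh(OFF[u], OFF[v]) == 1) { comp[v] = ncomp; q.push(v); }
      }
    }
    ncomp++;
  }
  return ncomp;
}

static inline bool is_simple(const int *nb) {
  return t26(nb) == 1 && t6(nb) == 1;
}

static inline int fg_neighbours(const int *nb) {
  int s = 0;
  for (int i = 0; i < 26; i++) s += nb[i];
  return s;
}

// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector vol, IntegerVector dims) {
  int K = dims[0], M = dims[1], N = dims[2];
  std::vector<int> img(vol.begin(), vol.end());
  int nb[26];
  // face-direction offsets for the six directional sub-iterations
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (int z = 0; z < N; z++)
        for (int y = 0; y < M; y++)
          for (int x = 0; x < K; x++) {
            int id = idx3(x, y, z, K, M);
            if (!img[id]) continue;
            int bx = x + dirs[d][0], by = y + dirs[d][1], bz = z + dirs[d][2];
            int bval = 0;
            if (bx >= 0 && by >= 0 && bz >= 0 && bx < K && by < M && bz < N)
              bval = img[idx3(bx, by, bz, K, M)];
            if (bval) continue;               // not a border point in d
            neighbourhood(img.data(), x, y, z, K, M, N, nb);
            int nn = fg_neighbours(nb);
            if (nn <= 1) continue;            // endpoint: keep
            if (!is_simple(nb)) continue;
            cand.push_back(id);
          }
      // sequential re-check: deleting earlier candidates can make later
      // ones non-simple, so each is re-verified against the current image
      for (size_t i = 0; i < cand.size(); i++) {
        int id = cand[i];
        int z = id / (K * M), r = id % (K * M);
        int y = r / K, x = r % K;
        neighbourhood(img.data(), x, y, z, K, M, N, nb);
        if (fg_neighbours(nb) <= 1) continue;
        if (!is_simple(nb)) continue;
        img[id] = 0;
        changed = true;
      }
    }
  }
  IntegerVector out(vol.size());
  std::copy(img.begin(), img.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
bool cpp_is_simple_point(IntegerVector vol, IntegerVector dims,
                         int x, int y, int z) {
  int K = dims[0], M = dims[1], N = dims[2];
  std::vector<int> img(vol.begin(), vol.end());
  int nb[26];
  neighbourhood(img.data(), x, y, z, K, M, N, nb);
  return is_simple(nb);
}

// Connected-component labelling, 6 or 26 connectivity. Labels are assigned
// in raster-scan order of each component's first voxel, so output is
// deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector vol, IntegerVector dims,
                                   int connectivity) {
  init_offsets();
  int K = dims[0], M = dims[1], N = dims[2];
  int n = K * M * N;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int id = 0; id < n; id++) {
    if (!vol[id] || lab[id]) continue;
    next++;
    lab[id] = next;
    q.push(id);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      int z = u / (K * M), r = u % (K * M);
      int y = r / K, x = r % K;
      for (int c = 0; c < 26; c++) {
        int dx = OFF[c][0], dy = OFF[c][1], dz = OFF[c][2];
        if (connectivity == 6 && abs(dx) + abs(dy) + abs(dz) != 1) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= K || yy >= M || zz >= N)
          continue;
        int v = idx3(xx, yy, zz, K, M);
        if (vol[v] && !lab[v]) { lab[v] = next; q.push(v); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Number of foreground voxels among the 26-neighbours of every voxel.
// [[Rcpp::export]]
IntegerVector cpp_neighbour_counts(IntegerVector vol, IntegerVector dims) {
  init_offsets();
  int K = dims[0], M = dims[1], N = dims[2];
  int n = K * M * N;
  IntegerVector cnt(n, 0);
  for (int id = 0; id < n; id++) {
    if (!vol[id]) continue;
    int z = id / (K * M), r = id % (K * M);
    int y = r / K, x = r % K;
    int s = 0;
    for (int c = 0; c < 26; c++) {
      int xx = x + OFF[c][0], yy = y + OFF[c][1], zz = z + OFF[c][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= K || yy >= M || zz >= N)
        continue;
      s += vol[idx3(xx, yy, zz, K, M)];
    }
    cnt[id] = s;
  }
  cnt.attr("dim") = dims;
  return cnt;
}
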