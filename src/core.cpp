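#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Column-major voxel index helpers. dims = (n1, n2, n3); axis 1 is vertical.
static inline R_xlen_t vidx(int i, int j, int k, const int* d) {
  return (R_xlen_t)i + (R_xlen_t)d[0] * ((R_xlen_t)j + (R_xlen_t)d[1] * (R_xlen_t)k);
}

// 26-neighbourhood offsets
static const int NB26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};

// ---------------------------------------------------------------------------
// 26-connected component labeling (BFS)
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        R_xlen_t p = vidx(i, j, k, d);
        if (!mask[p] || lab[p]) continue;
        ++cur;
        lab[p] = cur;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          R_xlen_t q = stack.back(); stack.pop_back();
          int qi = (int)(q % d[0]);
          int qj = (int)((q / d[0]) % d[1]);
          int qk = (int)(q / ((R_xlen_t)d[0] * d[1]));
          for (int m = 0; m < 26; ++m) {
            int a = qi + NB26[m][0], b = qj + NB26[m][1], c = qk + NB26[m][2];
            if (a < 0 || b < 0 || c < 0 || a >= d[0] || b >= d[1] || c >= d[2]) continue;
            R_xlen_t r = vidx(a, b, c, d);
            if (mask[r] && !lab[r]) { lab[r] = cur; stack.push_back(r); }
          }
        }
      }
  lab.attr("nlab") = cur;
  return lab;
}

// ---------------------------------------------------------------------------
// Per-label voxel counts and bounding boxes (1-based inclusive)
// [[Rcpp::export]]
List cpp_label_stats(IntegerVector lab, IntegerVector dims, int nlab) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  IntegerVector cnt(nlab, 0);
  IntegerMatrix lo(nlab, 3), hi(nlab, 3);
  NumericMatrix centroid(nlab, 3);
  for (int m = 0; m < nlab; ++m)
    for (int a = 0; a < 3; ++a) { lo(m, a) = INT_MAX; hi(m, a) = -1; }
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int l = lab[vidx(i, j, k, d)];
        if (!l) continue;
        int m = l - 1;
        cnt[m]++;
        int c[3] = {i, j, k};
        for (int a = 0; a < 3; ++a) {
          if (c[a] < lo(m, a)) lo(m, a) = c[a];
          if (c[a] > hi(m, a)) hi(m, a) = c[a];
          centroid(m, a) += c[a];
        }
      }
  for (int m = 0; m < nlab; ++m)
    for (int a = 0; a < 3; ++a) {
      lo(m, a) += 1; hi(m, a) += 1;  // 1-based for R
      if (cnt[m] > 0) centroid(m, a) = centroid(m, a) / cnt[m] + 1.0;
    }
  return List::create(_["count"] = cnt, _["lo"] = lo, _["hi"] = hi,
                      _["centroid"] = centroid);
}

// ---------------------------------------------------------------------------
// Surface area by the coarea formula: Gaussian-smooth the binary indicator and
// integrate the gradient magnitude. Returns area in voxel^2 units.
static double surf_subvol(const std::vector<double>& bin, const int* sd, double sigma) {
  int R = (int)std::ceil(4.0 * sigma);
  std::vector<double> kern(2 * R + 1);
  double s = 0.0;
  for (int t = -R; t <= R; ++t) { kern[t + R] = std::exp(-0.5 * t * t / (sigma * sigma)); s += kern[t + R]; }
  for (double& w : kern) w /= s;
  R_xlen_t n = (R_xlen_t)sd[0] * sd[1] * sd[2];
  std::vector<double> a(bin), b(n);
  // separable convolution along each axis (zero padding implicit: subvolume is padded)
  for (int axis = 0; axis < 3; ++axis) {
    for (int k = 0; k < sd[2]; ++k)
      for (int j = 0; j < sd[1]; ++j)
        for (int i = 0; i < sd[0]; ++i) {
          double acc = 0.0;
          for (int t = -R; t <= R; ++t) {
            int c[3] = {i, j, k};
            c[axis] += t;
            if (c[axis] < 0 || c[axis] >= sd[axis]) continue;
            acc += kern[t + R] * a[vidx(c[0], c[1], c[2], sd)];
          }
          b[vidx(i, j, k, sd)] = acc;
        }
    std::swap(a, b);
  }
  // central-difference gradient magnitude, summed
  double area = 0.0;
  for (int k = 1; k < sd[2] - 1; ++k)
    for (int j = 1; j < sd[1] - 1; ++j)
      for (int i = 1; i < sd[0] - 1; ++i) {
        double gx = 0.5 * (a[vidx(i + 1, j, k, sd)] - a[vidx(i - 1, j, k, sd)]);
        double gy = 0.5 * (a[vidx(i, j + 1, k, sd)] - a[vidx(i, j - 1, k, sd)]);
        double gz = 0.5 * (a[vidx(i, j, k + 1, sd)] - a[vidx(i, j, k - 1, sd)]);
        area += std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return area;
}

// Per-label smoothed surface areas (voxel^2), cropping each label's padded box.
// [[Rcpp::export]]
NumericVector cpp_surface_by_label(IntegerVector lab, IntegerVector dims, int nlab,
                                   IntegerMatrix lo, IntegerMatrix hi, double sigma) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  int pad = (int)std::ceil(4.0 * sigma) + 2;
  NumericVector out(nlab);
  for (int m = 0; m < nlab; ++m) {
    int sd[3], off[3];
    for (int a = 0; a < 3; ++a) {
      off[a] = lo(m, a) - 1 - pad;
      sd[a] = hi(m, a) - lo(m, a) + 1 + 2 * pad;
    }
    std::vector<double> bin((R_xlen_t)sd[0] * sd[1] * sd[2], 0.0);
    for (int k = lo(m, 2) - 1; k <= hi(m, 2) - 1; ++k)
      for (int j = lo(m, 1) - 1; j <= hi(m, 1) - 1; ++j)
        for (int i = lo(m, 0) - 1; i <= hi(m, 0) - 1; ++i)
          if (lab[vidx(i, j, k, d)] == m + 1)
            bin[vidx(i - off[0], j - off[1], k - off[2], sd)] = 1.0;
    out[m] = surf_subvol(bin, sd, sigma);
  }
  return out;
}

// Whole-mask smoothed surface area (voxel^2)
// [[Rcpp::export]]
double cpp_surface_mask(LogicalVector mask, IntegerVector dims, double sigma) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  int pad = (int)std::ceil(4.0 * sigma) + 2;
  int sd[3] = {d[0] + 2 * pad, d[1] + 2 * pad, d[2] + 2 * pad};
  std::vector<double> bin((R_xlen_t)sd[0] * sd[1] * sd[2], 0.0);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i)
        if (mask[vidx(i, j, k, d)])
          bin[vidx(i + pad, j + pad, k + pad, sd)] = 1.0;
  return surf_subvol(bin, sd, sigma);
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning (curve skeleton).
// A voxel is simple iff it has exactly one 26-connected object component in its
// 26-neighbourhood and exactly one 6-connected background component in its
// 18-neighbourhood that touches a face neighbour (Malandain-Bertrand for the
// (26,6) connectivity pair).
static inline int noff(int dx, int dy, int dz) { return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1)); }

static bool is_simple(const bool* nb) {
  // nb: 27 bools, object membership, center nb[13]
  // object components (26-connectivity) among the 26 neighbours
  bool seen[27] = {false};
  int ncomp = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !nb[p] || seen[p]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    std::vector<int> st{p};
    seen[p] = true;
    while (!st.empty()) {
      int q = st.back(); st.pop_back();
      int qx = q % 3 - 1, qy = (q / 3) % 3 - 1, qz = q / 9 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ax = qx + dx, ay = qy + dy, az = qz + dz;
            if (ax < -1 || ax > 1 || ay < -1 || ay > 1 || az < -1 || az > 1) continue;
            int r = noff(ax, ay, az);
            if (r == 13 || !nb[r] || seen[r]) continue;
            seen[r] = true;
            st.push_back(r);
          }
    }
  }
  if (ncomp != 1) return false;
  // background 6-components within the 18-neighbourhood touching a face neighbour
  bool inN18[27], bseen[27] = {false};
  for (int p = 0; p < 27; ++p) {
    int px = p % 3 - 1, py = (p / 3) % 3 - 1, pz = p / 9 - 1;
    int nz = (px != 0) + (py != 0) + (pz != 0);
    inN18[p] = (p != 13) && nz <= 2;
  }
  int nbg = 0;
  static const int F6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int f = 0; f < 6; ++f) {
    int p = noff(F6[f][0], F6[f][1], F6[f][2]);
    if (nb[p] || bseen[p]) continue;
    ++nbg;
    if (nbg > 1) return false;
    std::vector<int> st{p};
    bseen[p] = true;
    while (!st.empty()) {
      int q = st.back(); st.pop_back();
      int qx = q % 3 - 1, qy = (q / 3) % 3 - 1, qz = q / 9 - 1;
      for (int g = 0; g < 6; ++g) {
        int ax = qx + F6[g][0], ay = qy + F6[g][1], az = qz + F6[g][2];
        if (ax < -1 || ax > 1 || ay < -1 || ay > 1 || az < -1 || az > 1) continue;
        int r = noff(ax, ay, az);
        if (!inN18[r] || nb[r] || bseen[r]) continue;
        bseen[r] = true;
        st.push_back(r);
      }
    }
  }
  return nbg == 1;
}

static void fill_nb(const LogicalVector& mask, const int* d, int i, int j, int k, bool* nb) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int a = i + dx, b = j + dy, c = k + dz;
        bool v = false;
        if (a >= 0 && b >= 0 && c >= 0 && a < d[0] && b < d[1] && c < d[2])
          v = mask[vidx(a, b, c, d)];
        nb[noff(dx, dy, dz)] = v;
      }
}

static int count_obj_neighbors(const bool* nb) {
  int c = 0;
  for (int p = 0; p < 27; ++p) if (p != 13 && nb[p]) ++c;
  return c;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask_in, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  LogicalVector mask = clone(mask_in);
  static const int DIR[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool nb[27];
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (int k = 0; k < d[2]; ++k)
        for (int j = 0; j < d[1]; ++j)
          for (int i = 0; i < d[0]; ++i) {
            R_xlen_t p = vidx(i, j, k, d);
            if (!mask[p]) continue;
            int a = i + DIR[dir][0], b = j + DIR[dir][1], c = k + DIR[dir][2];
            bool border = !(a >= 0 && b >= 0 && c >= 0 && a < d[0] && b < d[1] && c < d[2]) ||
                          !mask[vidx(a, b, c, d)];
            if (!border) continue;
            fill_nb(mask, d, i, j, k, nb);
            if (count_obj_neighbors(nb) <= 1) continue;  // endpoint
            if (is_simple(nb)) cand.push_back(p);
          }
      // sequential deletion with recheck keeps topology exact
      for (R_xlen_t p : cand) {
        int i = (int)(p % d[0]);
        int j = (int)((p / d[0]) % d[1]);
        int k = (int)(p / ((R_xlen_t)d[0] * d[1]));
        fill_nb(mask, d, i, j, k, nb);
        if (count_obj_neighbors(nb) <= 1) continue;
        if (is_simple(nb)) { mask[p] = false; changed = true; }
      }
    }
  }
  return mask;
}

// ---------------------------------------------------------------------------
// Seeded region growing: FIFO flood fill (26-connectivity); accept a voxel if
// its intensity is within tol of the running region mean.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dims,
                              IntegerMatrix seeds, double tol) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector out(n, false);
  std::queue<R_xlen_t> fifo;
  double sum = 0.0;
  R_xlen_t cnt = 0;
  for (int s = 0; s < seeds.nrow(); ++s) {
    R_xlen_t p = vidx(seeds(s, 0) - 1, seeds(s, 1) - 1, seeds(s, 2) - 1, d);
    if (!out[p]) {
      out[p] = true;
      sum += vol[p]; cnt++;
      fifo.push(p);
    }
  }
  while (!fifo.empty()) {
    R_xlen_t q = fifo.front(); fifo.pop();
    int qi = (int)(q % d[0]);
    int qj = (int)((q / d[0]) % d[1]);
    int qk = (int)(q / ((R_xlen_t)d[0] * d[1]));
    double mean = sum / cnt;
    for (int m = 0; m < 26; ++m) {
      int a = qi + NB26[m][0], b = qj + NB26[m][1], c = qk + NB26[m][2];
      if (a < 0 || b < 0 || c < 0 || a >= d[0] || b >= d[1] || c >= d[2]) continue;
      R_xlen_t r = vidx(a, b, c, d);
      if (out[r]) continue;
      if (std::fabs(vol[r] - mean) <= tol) {
        out[r] = true;
        sum += vol[r]; cnt++;
        fifo.push(r);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Binary dilation / erosion with the full 3x3x3 structuring element
// [[Rcpp::export]]
LogicalVector cpp_dilate26(LogicalVector mask, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector out(n, false);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        R_xlen_t p = vidx(i, j, k, d);
        if (!mask[p]) continue;
        out[p] = true;
        for (int m = 0; m < 26; ++m) {
          int a = i + NB26[m][0], b = j + NB26[m][1], c = k + NB26[m][2];
          if (a < 0 || b < 0 || c < 0 || a >= d[0] || b >= d[1] || c >= d[2]) continue;
          out[vidx(a, b, c, d)] = true;
        }
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_erode26(LogicalVector mask, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector out(n, false);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        R_xlen_t p = vidx(i, j, k, d);
        if (!mask[p]) continue;
        bool keep = true;
        for (int m = 0; m < 26 && keep; ++m) {
          int a = i + NB26[m][0], b = j + NB26[m][1], c = k + NB26[m][2];
          if (a < 0 || b < 0 || c < 0 || a >= d[0] || b >= d[1] || c >= d[2]) { keep = false; break; }
          if (!mask[vidx(a, b, c, d)]) keep = false;
        }
        out[p] = keep;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Euler characteristic of the cubical complex spanned by the voxel centers:
// chi = V - E + F - C (vertices, axis edges, unit squares, unit cubes).
// [[Rcpp::export]]
double cpp_euler(LogicalVector mask, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  long long V = 0, E = 0, F = 0, C = 0;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        if (!mask[vidx(i, j, k, d)]) continue;
        ++V;
        bool x = i + 1 < d[0] && mask[vidx(i + 1, j, k, d)];
        bool y = j + 1 < d[1] && mask[vidx(i, j + 1, k, d)];
        bool z = k + 1 < d[2] && mask[vidx(i, j, k + 1, d)];
        E += x + y + z;
        bool xy = x && y && mask[vidx(i + 1, j + 1, k, d)];
        bool xz = x && z && mask[vidx(i + 1, j, k + 1, d)];
        bool yz = y && z && mask[vidx(i, j + 1, k + 1, d)];
        F += xy + xz + yz;
        if (xy && xz && yz && mask[vidx(i + 1, j + 1, k + 1, d)]) ++C;
      }
  return (double)(V - E + F - C);
}

// ---------------------------------------------------------------------------
// Degree (number of 26-neighbours inside the mask) for every voxel of a mask;
// used by the skeleton-graph builder.
// [[Rcpp::export]]
IntegerVector cpp_degree26(LogicalVector mask, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector deg(n, 0);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        R_xlen_t p = vidx(i, j, k, d);
        if (!mask[p]) { deg[p] = NA_INTEGER; continue; }
        int c = 0;
        for (int m = 0; m < 26; ++m) {
          int a = i + NB26[m][0], b = j + NB26[m][1], cc = k + NB26[m][2];
          if (a < 0 || b < 0 || cc < 0 || a >= d[0] || b >= d[1] || cc >= d[2]) continue;
          if (mask[vidx(a, b, cc, d)]) ++c;
        }
        deg[p] = c;
      }
  return deg;
}
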